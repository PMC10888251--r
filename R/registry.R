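#' @include AllClasses.R AllGenerics.R
NULL

# registry is parsed once per session from the packaged JSON
.registryCache <- new.env(parent = emptyenv())

.registry <- function() {
  if (!is.null(.registryCache$db)) return(.registryCache$db)
  path <- system.file("extdata", "enzymes.json", package = "uniCycle",
                      mustWork = TRUE)
  db <- jsonlite::read_json(path, simplifyVector = FALSE)
  db <- db[!startsWith(names(db), "_")]
  .registryCache$db <- db
  db
}

#' Registered enzyme identifiers
#'
#' @return character vector of the identifiers accepted by [loadEnzyme()]
#' @export
#' @examples
#' listEnzymes()
listEnzymes <- function() names(.registry())

#' Construct a reaction environment
#'
#' @param substrate substrate concentration, M
#' @param product product concentration, M
#' @param buffer buffer concentration, M (carbonic anhydrase schemes)
#' @param enzyme total enzyme concentration, M
#' @param temperature free-text label, never used numerically
#' @return a [CycleEnvironment]
#' @export
cycleEnvironment <- function(substrate, product, buffer = NA_real_,
                             enzyme = NA_real_, temperature = "") {
  new("CycleEnvironment", substrate = as.numeric(substrate),
      product = as.numeric(product), buffer = as.numeric(buffer),
      enzyme = as.numeric(enzyme), temperature = as.character(temperature))
}

#' Construct a rate set
#'
#' @param k numeric vector of 2n pseudo-first-order rate constants, 1/s;
#'   odd positions forward, even positions backward
#' @return a [RateSet]
#' @export
#' @examples
#' rateSet(c(400, 7000, 2000, 6000, 60000, 90000, 4000, 25.6))
rateSet <- function(k) {
  k <- as.numeric(k)
  if (length(k) %% 2L != 0L)
    stop("a rate set needs an even number of constants (2 per catalytic step)")
  new("RateSet", k = unname(k), nStates = as.integer(length(k) / 2L))
}

.paramsFromRecord <- function(name, rec, variant = NULL) {
  if (!is.null(variant)) {
    if (is.null(rec$variants[[variant]]))
      stop(sprintf("enzyme \"%s\" has no parameter variant \"%s\"", name, variant))
    v <- rec$variants[[variant]]
    rec$second_order <- v$second_order
    rec$first_order <- v$first_order
    rec$printed_first_order <- v$printed_first_order
  }
  so <- vapply(rec$second_order, function(x) as.numeric(x$value), numeric(1))
  lig <- vapply(rec$second_order, function(x) as.character(x$ligand), character(1))
  fo <- vapply(rec$first_order, as.numeric, numeric(1))
  pfo <- if (length(rec$printed_first_order))
    vapply(rec$printed_first_order, as.numeric, numeric(1)) else
    stats::setNames(numeric(0), character(0))
  env <- rec$environment
  ref <- if (length(rec$reference))
    vapply(rec$reference, as.numeric, numeric(1)) else
    stats::setNames(numeric(0), character(0))
  new("EnzymeParams",
      name = name,
      fullName = as.character(rec$full_name),
      nStates = as.integer(rec$n_states),
      schemeVariant = as.character(rec$scheme_variant),
      secondOrder = so,
      bindingLigand = lig,
      firstOrder = fo,
      printedFirstOrder = pfo,
      environment = cycleEnvironment(
        substrate = env$substrate, product = env$product,
        buffer = if (is.null(env$buffer)) NA_real_ else env$buffer,
        enzyme = if (is.null(env$enzyme)) NA_real_ else env$enzyme,
        temperature = if (is.null(env$temperature)) "" else env$temperature),
      keqConvention = as.character(rec$keq_convention),
      reference = ref)
}

#' Load a registered enzyme parameter set
#'
#' Returns the curated parameter set exactly as printed in the source
#' kinetic table: second-order binding constants with their ligand,
#' first-order constants, the printed pseudo-first-order values, and the
#' reference concentrations.
#'
#' @param name one of [listEnzymes()]
#' @param variant optional alternative parameter column where the source
#'   prints more than one (ketosteroid isomerase: "ref89")
#' @return an [EnzymeParams]
#' @export
#' @examples
#' tpi <- loadEnzyme("tpi")
#' rateConstants(referenceRateSet(tpi))
loadEnzyme <- function(name, variant = NULL) {
  db <- .registry()
  if (!name %in% names(db))
    stop(sprintf("unknown enzyme \"%s\"; valid identifiers are: %s",
                 name, paste(names(db), collapse = ", ")))
  .paramsFromRecord(name, db[[name]], variant = variant)
}

#' Build the pseudo-first-order rate set for an environment
#'
#' Binding transitions are converted by k_i = k_i* x [ligand] (substrate,
#' product or, in the buffer-modified carbonic anhydrase scheme, buffer
#' for both k7 and k8); first-order constants pass through unchanged.
#'
#' @param params an [EnzymeParams]
#' @param env a [CycleEnvironment]; defaults to the enzyme's reference
#'   environment
#' @return a [RateSet]
#' @export
#' @examples
#' buildRateSet(loadEnzyme("tpi"))  # k1 = 1e7 * 4e-5 = 400 1/s
buildRateSet <- function(params, env = params@environment) {
  stopifnot(is(params, "EnzymeParams"), is(env, "CycleEnvironment"))
  n2 <- 2L * params@nStates
  k <- numeric(n2)
  labs <- paste0("k", seq_len(n2))
  conc <- c(S = env@substrate, P = env@product, B = env@buffer)
  for (i in seq_len(n2)) {
    lab <- labs[i]
    if (lab %in% names(params@secondOrder)) {
      lig <- params@bindingLigand[[lab]]
      if (is.na(conc[[lig]]))
        stop(sprintf("environment lacks the %s concentration required by %s",
                     lig, lab))
      if (conc[[lig]] <= 0)
        stop(sprintf("%s concentration must be positive to build %s",
                     lig, lab))
      k[i] <- params@secondOrder[[lab]] * conc[[lig]]
    } else {
      k[i] <- params@firstOrder[[lab]]
    }
  }
  rateSet(k)
}

#' Reference rate set exactly as printed
#'
#' The pseudo-first-order rate set of the enzyme's reference state, using
#' the printed pseudo-first-order values for the binding transitions
#' rather than re-deriving them, so that every constant matches the
#' source table digit for digit.
#'
#' @param params an [EnzymeParams]
#' @return a [RateSet]
#' @export
referenceRateSet <- function(params) {
  stopifnot(is(params, "EnzymeParams"))
  n2 <- 2L * params@nStates
  labs <- paste0("k", seq_len(n2))
  built <- buildRateSet(params)
  k <- built@k
  for (lab in names(params@printedFirstOrder))
    k[match(lab, labs)] <- params@printedFirstOrder[[lab]]
  rateSet(k)
}

#' Write an enzyme parameter set to a JSON file
#'
#' The file uses the same self-describing record layout as the packaged
#' registry, so [readEnzymeParams()] round-trips every numeric field
#' bit-identically.
#'
#' @param params an [EnzymeParams]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeEnzymeParams <- function(params, path) {
  stopifnot(is(params, "EnzymeParams"))
  env <- params@environment
  rec <- list(
    full_name = params@fullName,
    n_states = params@nStates,
    scheme_variant = params@schemeVariant,
    keq_convention = params@keqConvention,
    second_order = stats::setNames(lapply(names(params@secondOrder), function(l)
      list(value = params@secondOrder[[l]], ligand = params@bindingLigand[[l]])),
      names(params@secondOrder)),
    first_order = as.list(params@firstOrder),
    printed_first_order = as.list(params@printedFirstOrder),
    environment = list(substrate = env@substrate, product = env@product,
                       buffer = env@buffer, enzyme = env@enzyme,
                       temperature = env@temperature),
    reference = as.list(params@reference)
  )
  out <- stats::setNames(list(rec), params@name)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an enzyme parameter set from a JSON file
#'
#' @param path a file written by [writeEnzymeParams()] (or hand-written in
#'   the same layout: one named record with explicit field names;
#'   scientific notation welcome)
#' @param name which record to read; defaults to the first
#' @return an [EnzymeParams]
#' @export
readEnzymeParams <- function(path, name = NULL) {
  db <- jsonlite::read_json(path, simplifyVector = FALSE)
  db <- db[!startsWith(names(db), "_")]
  if (is.null(name)) name <- names(db)[1]
  if (!name %in% names(db))
    stop(sprintf("no record \"%s\" in %s", name, path))
  .paramsFromRecord(name, db[[name]])
}
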