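#' @useDynLib diallelGS, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var sd cor rnorm runif rbinom rchisq optim optimHess
#'   optimize pchisq setNames ar
#' @importFrom utils read.csv write.csv
#' @importFrom graphics plot boxplot
#' @importFrom grDevices png dev.off
NULL

# Deterministic per-stage seed streams derived from one global integer seed.
# Kept below 2^31 so they remain valid R integers.
stage_seed <- function(seed, stage) {
  offsets <- c(pedigree = 11L, genotypes = 23L, phenotypes = 37L, qc = 53L,
               split = 71L, mcmc = 89L, markers = 101L, misc = 113L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 7919 + off * 104729) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Round half away from zero at `digits` decimals (R's round() is half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dgs_log <- function(..., verbose = getOption("diallelGS.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[diallelGS] ", ...)
  invisible(NULL)
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
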