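# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals never disturb the
#' caller's RNG stream.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Per-stage child seeds derived from one master seed by fixed offsets, kept
# below 2^31 so they remain valid R integers.
child_seed <- function(master, stage) {
  offsets <- c(haplotypes = 101L, covariates = 211L, noise = 307L,
               clones = 401L, impute = 503L, features = 601L,
               gwas = 701L, fisher = 809L)
  off <- offsets[[stage]]
  as.integer((as.numeric(master) * 1009 + off) %% 2147483647)
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# strip an allele suffix ("IGHV3-23*01" -> "IGHV3-23")
strip_allele <- function(x) sub("\\*.*$", "", x)

# clamp p-values into (0, 1] as required downstream
clamp_p <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)
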