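# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# commercial rounding (half away from zero), as used in the report tables
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage of part in whole, rounded half-up to 2 decimals; 0 when whole == 0
pct2 <- function(part, whole) {
  if (length(whole) == 1L && whole == 0) return(rep(0, length(part)))
  round_half_up(100 * part / whole, 2L)
}

logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

DNA_BASES <- c("A", "C", "G", "T")

check_dna <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad))
    stop(sprintf("%s contains characters outside {A,C,G,T%s}: e.g. '%s'",
                 what, if (allow_n) ",N" else "",
                 substr(x[which(bad)[1L]], 1L, 30L)), call. = FALSE)
  invisible(x)
}

# tag -> count named integer vector from a character multiset or a named vector
as_tag_counts <- function(x) {
  if (!is.null(names(x)) && is.numeric(x)) {
    counts <- as.integer(round(x))
    names(counts) <- names(x)
    return(counts[counts > 0L])
  }
  if (is.character(x)) {
    tab <- table(x)
    return(setNames(as.integer(tab), names(tab)))
  }
  stop("expected a character vector of reads or a named count vector",
       call. = FALSE)
}
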