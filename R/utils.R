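# Internal helpers shared across modules.

# Deterministic per-module substream seed.  A single top-level seed plus a
# polynomial hash of the module name gives each generator an independent
# stream, so adding one generator never perturbs another's output.
substream_seed <- function(seed, module) {
  stopifnot(is.numeric(seed), length(seed) == 1L, !is.na(seed))
  h <- 0
  for (code in utf8ToInt(module)) h <- (h * 31 + code) %% 1000000007
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

with_substream <- function(seed, module, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, module))
  force(code)
}

# Robust marker-noise SD from lag-1 differences so genuine copy-number steps
# do not inflate the estimate: mad(diff(x)) / sqrt(2).
robust_noise_sd <- function(x) {
  d <- diff(x[is.finite(x)])
  if (length(d) < 2) return(0)
  stats::mad(d) / sqrt(2)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# 1-based inclusive interval overlap length (0 when disjoint).
overlap_bp <- function(start1, end1, start2, end2) {
  pmax(0, pmin(end1, end2) - pmax(start1, start2) + 1)
}
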