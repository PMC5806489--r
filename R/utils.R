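# internal helpers

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. seed = NULL leaves the stream alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# midpoint of an interval set (0-based bp, one per record)
interval_midpoints <- function(x) floor((x$start + x$end) / 2)
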