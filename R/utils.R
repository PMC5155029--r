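# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Canonical nucleotide form: uppercase, RNA U mapped to T.
canonical_seq <- function(x) {
  x <- chartr("u", "U", x)
  chartr("U", "T", toupper(x))
}

assert_nucleotides <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N}: %s",
                 what, substr(x[bad][1L], 1L, 40L)), call. = FALSE)
  }
  invisible(x)
}

# Equal-length Hamming distance for a pair of strings (R-side, used in
# small-scale code paths and as readable reference). N mismatches every
# base including N, matching the network edge rule.
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) return(NA_integer_)
  ia <- utf8ToInt(a)
  ib <- utf8ToInt(b)
  n_code <- utf8ToInt("N")
  sum(ia != ib | ia == n_code)
}

# condition helpers ---------------------------------------------------------

bcrmrd_error <- function(msg, class) {
  stop(structure(class = c(class, "bcrmrd_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
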