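# internal helpers shared across modules

# Evaluate `code` under set.seed(seed) without clobbering the caller's RNG
# stream; seed = NULL leaves the ambient stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}

# half-open interval membership, vectorised on x
`%within%` <- function(x, iv) x >= iv[1] & x < iv[2]

# sum of a logical/numeric matrix over the k x k window centred on each cell
# (edges truncated), via an integral image; k must be odd.
box_sum <- function(m, k) {
  stopifnot(k %% 2L == 1L)
  r <- (k - 1L) %/% 2L
  nr <- nrow(m); nc <- ncol(m)
  a <- apply(m, 2L, cumsum)
  if (nr == 1L) a <- matrix(a, nrow = 1L)
  a <- t(apply(a, 1L, cumsum))
  if (nc == 1L) a <- matrix(a, ncol = 1L)
  # pad with a leading zero row/col so a[i+1, j+1] = sum(m[1:i, 1:j])
  ap <- matrix(0, nr + 1L, nc + 1L)
  ap[-1L, -1L] <- a
  i <- seq_len(nr); j <- seq_len(nc)
  r2 <- pmin(i + r, nr) + 1L; r1 <- pmax(i - r, 1L)
  c2 <- pmin(j + r, nc) + 1L; c1 <- pmax(j - r, 1L)
  ap[r2, c2] - ap[r1, c2] - ap[r2, c1] + ap[r1, c1]
}
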