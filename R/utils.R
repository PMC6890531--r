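# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Wrap angles to the principal interval (-pi, pi].
wrap_pi <- function(x) {
  r <- (x + pi) %% (2 * pi) - pi
  r[r == -pi] <- pi
  r
}

# Centered running maximum (van Herk two-pass algorithm, fully vectorized).
# Window is `w` samples, centered; shrinks at the edges.
running_max <- function(x, w) {
  n <- length(x)
  stopifnot(w >= 1)
  if (w == 1 || n == 1) return(x)
  h1 <- (w - 1) %/% 2
  h2 <- w - 1 - h1
  # pad so that block boundaries do not truncate windows
  pad <- c(rep(-Inf, h1), x, rep(-Inf, h2 + w))
  m <- length(pad)
  nb <- ceiling(m / w)
  pad <- c(pad, rep(-Inf, nb * w - m))
  blk <- matrix(pad, nrow = w)
  fwd <- apply(blk, 2, cummax)
  bwd <- apply(blk[w:1, , drop = FALSE], 2, cummax)[w:1, , drop = FALSE]
  fwd <- as.vector(fwd)
  bwd <- as.vector(bwd)
  # window i (1-based on x) spans pad indices [i, i + w - 1]
  i <- seq_len(n)
  lo <- i
  hi <- i + w - 1
  out <- pmax(bwd[lo], fwd[hi])
  # edge shrink: -Inf padding never wins unless the window is all padding
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
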