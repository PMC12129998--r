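#' @keywords internal
"_PACKAGE"

# Numerically safe softmax (max-subtraction). Attention rows and ranking
# distributions are downstream contracts, so this is the single softmax used
# everywhere in the package.
softmax <- function(x) {
  if (length(x) == 0L) stop("softmax of an empty vector is undefined")
  e <- exp(x - max(x))
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

leaky_relu <- function(x, slope = 0.2) ifelse(x >= 0, x, slope * x)

elu <- function(x) ifelse(x >= 0, x, exp(x) - 1)

relu <- function(x) pmax(x, 0)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(sprintf(...), call. = FALSE)

# ---- Deterministic pseudo-randomness independent of R's global RNG ---------
#
# Token/relation embeddings and frozen encoder weights must be reproducible
# across sessions without touching .Random.seed. A Lehmer (Park-Miller) LCG
# over the Mersenne prime 2^31-1 is used; all arithmetic stays in doubles
# (exactly representable below 2^53).

LEHMER_M <- 2147483647
LEHMER_A <- 48271

lehmer_next <- function(state) (LEHMER_A * state) %% LEHMER_M

# n uniforms in (0,1) from an integer state in [1, 2^31-2]
lehmer_runif <- function(n, state) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    state <- lehmer_next(state)
    out[i] <- state / LEHMER_M
  }
  list(values = out, state = state)
}

# Standard normals via Box-Muller on Lehmer uniforms.
lehmer_rnorm <- function(n, state) {
  m <- ceiling(n / 2) * 2
  u <- lehmer_runif(m, state)
  u1 <- u$values[seq(1, m, by = 2)]
  u2 <- u$values[seq(2, m, by = 2)]
  r <- sqrt(-2 * log(pmax(u1, 1e-12)))
  z <- c(r * cos(2 * pi * u2), r * sin(2 * pi * u2))
  list(values = z[seq_len(n)], state = u$state)
}

# Polynomial rolling hash of a UTF-8 string into [1, 2^31-2]; mixed with a
# caller seed so distinct embedders give distinct vectors for the same token.
string_hash <- function(x, seed = 0) {
  h <- (seed %% LEHMER_M) + 1
  for (b in utf8ToInt(x)) {
    h <- (h * 131 + b) %% LEHMER_M
  }
  if (h <= 0) h <- 1
  h
}

# Deterministic embedding of a token: N(0, 1/d) entries so vectors have
# roughly unit norm at any dimension.
hash_embed <- function(token, dim, seed = 0) {
  st <- string_hash(token, seed)
  # burn a few states so nearby hashes decorrelate
  for (i in 1:3) st <- lehmer_next(st)
  lehmer_rnorm(dim, st)$values / sqrt(dim)
}

# Deterministic dense matrix of N(0, sd^2) entries keyed by (tag, seed).
hash_matrix <- function(nrow, ncol, tag, seed = 0, sd = 0.3) {
  st <- string_hash(tag, seed)
  for (i in 1:3) st <- lehmer_next(st)
  matrix(lehmer_rnorm(nrow * ncol, st)$values * sd, nrow = nrow, ncol = ncol)
}

# Deterministic random semi-orthogonal matrix (QR of a Gaussian draw with
# sign-fixed diagonal). Frozen projections in the encoder stack use this:
# orthogonal maps are well conditioned, so no direction of the token space
# is collapsed by an unlucky draw.
hash_orth <- function(nrow, ncol, tag, seed = 0, gain = 1) {
  n <- max(nrow, ncol)
  A <- hash_matrix(n, n, tag, seed, sd = 1)
  qr_ <- qr(A)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))), nrow = n)
  gain * Q[seq_len(nrow), seq_len(ncol), drop = FALSE]
}

# Stage seeds derived from one pipeline seed; keeps every stage independently
# reproducible and every derived seed below 2^31.
derive_seed <- function(seed, stage) {
  s <- (as.numeric(seed) %% LEHMER_M)
  (s * 2654435761 + string_hash(stage)) %% LEHMER_M
}

# Run code under a temporary R RNG seed, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed %% LEHMER_M)
  force(code)
}

# Column-mean pooling of a per-token encoding matrix; zero-row matrices pool
# to the zero vector (the designated empty-subgraph context).
pool_mean <- function(H, dim = ncol(H)) {
  if (is.null(H) || nrow(H) == 0L) return(numeric(dim))
  colMeans(H)
}

check_prob <- function(p, tol = 1e-9, what = "distribution") {
  if (any(p < -tol)) stop_arg("%s has negative entries", what)
  if (abs(sum(p) - 1) > tol) stop_arg("%s does not sum to 1 (sum = %.12f)", what, sum(p))
  invisible(TRUE)
}
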