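# Internal numerical and RNG helpers.

relu <- function(x) pmax(x, 0)

leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow for large |x|
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals never
#' perturb the caller's random stream.
#' @noRd
with_seed_ <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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
  }
  force(expr)
}

# Derive n child seeds from one parent seed; all < 2^31.
derive_seeds <- function(seed, n) {
  with_seed_(seed, sample.int(.Machine$integer.max - 1L, n))
}

# FNV-1a 32-bit hash of a character scalar, returned as 8-char hex.
# (Used for provenance config hashes.)
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  two16 <- 65536
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    h1 <- h %/% two16
    h0 <- h %% two16
    h <- (((h1 * p) %% two16) * two16 + h0 * p) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# XOR for doubles holding 32-bit unsigned values (bitwXor needs ints).
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 2147483648
  lo_a <- a %% 2147483648
  hi_b <- b %/% 2147483648
  lo_b <- b %% 2147483648
  xor_hi <- as.numeric(xor(hi_a > 0, hi_b > 0))
  xor_hi * 2147483648 + as.numeric(bitwXor(as.integer(lo_a), as.integer(lo_b)))
}

# scatter-add rows of `vals` into matrix M at (possibly repeated) row
# indices idx; returns updated M.
scatter_add <- function(M, idx, vals) {
  if (length(idx) == 0L) return(M)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(idx))
  agg <- rowsum(vals, group = idx, reorder = FALSE)
  rows <- as.integer(rownames(agg))
  M[rows, ] <- M[rows, , drop = FALSE] + agg
  M
}

# per-group max for a numeric vector, groups given as integer codes;
# returns vector aligned with x
group_max <- function(x, group, group_index) {
  gm <- vapply(group_index, function(ix) max(x[ix]), numeric(1))
  gm[group]
}

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
}
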