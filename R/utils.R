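# Internal numeric helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# 10 unordered diploid genotypes in fixed alphabetical order.
GENO10 <- matrix(c(
  "A", "A",  "A", "C",  "A", "G",  "A", "T",
  "C", "C",  "C", "G",  "C", "T",
  "G", "G",  "G", "T",
  "T", "T"), ncol = 2, byrow = TRUE)
GENO10_NAMES <- paste0(GENO10[, 1], GENO10[, 2])

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix, stable.
row_logsumexp <- function(x) {
  m <- apply(x, 1L, max)
  ok <- is.finite(m)
  out <- m
  if (any(ok)) out[ok] <- m[ok] + log(rowSums(exp(x[ok, , drop = FALSE] - m[ok])))
  out
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = genv)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

base_index <- function(b) {
  i <- match(b, BASES)
  if (anyNA(i)) stop("invalid base symbol: ", paste(unique(b[is.na(i)]), collapse = ", "))
  i
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

# Total variation distance between two probability vectors/matrices.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))
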