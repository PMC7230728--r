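# Order-m Markov backbone for synthetic genomes.
#
# Transition P(base | context) ~ p_base(base) * exp(self_bias * [base equals
# the last context base]), with p_base the symmetric composition
# (A=T=(1-gc)/2, C=G=gc/2). The self-repetition bias is invariant under
# complementation, so strand symmetry is preserved; the base composition fed
# into the matrix is recalibrated (1-d root find on the stationary
# distribution) so the realized stationary G+C equals the requested target.

.base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                              T = (1 - gc) / 2)

# transition matrix over 4^m contexts x 4 bases
.markov_matrix <- function(order, gc, self_bias) {
  bases <- c("A", "C", "G", "T")
  p <- .base_probs(gc)
  n_ctx <- 4L^max(order, 0L)
  T_ <- matrix(rep(p, each = n_ctx), nrow = n_ctx, ncol = 4L,
               dimnames = list(NULL, bases))
  if (order >= 1L && self_bias != 0) {
    last <- ((seq_len(n_ctx) - 1L) %% 4L) + 1L  # last base of each context
    for (b in 1:4) {
      T_[last == b, b] <- T_[last == b, b] * exp(self_bias)
    }
    T_ <- T_ / rowSums(T_)
  }
  T_
}

# stationary G+C of the induced context chain
.markov_stationary_gc <- function(T_, order) {
  if (order == 0L) return(sum(T_[1L, c("C", "G")]))
  n_ctx <- nrow(T_)
  P <- matrix(0, n_ctx, n_ctx)
  for (ctx in seq_len(n_ctx)) {
    for (b in 1:4) {
      nxt <- ((ctx - 1L) %% (n_ctx %/% 4L)) * 4L + b
      P[ctx, nxt] <- P[ctx, nxt] + T_[ctx, b]
    }
  }
  pi_ <- rep(1 / n_ctx, n_ctx)
  for (it in 1:400) pi_ <- pi_ %*% P
  pi_ <- as.numeric(pi_ / sum(pi_))
  last <- ((seq_len(n_ctx) - 1L) %% 4L) + 1L
  sum(pi_[last %in% c(2L, 3L)])  # contexts ending in C or G
}

# matrix whose stationary G+C hits the target
.calibrated_markov <- function(order, gc, self_bias) {
  if (order == 0L || self_bias == 0) return(.markov_matrix(order, gc, 0))
  f <- function(g) .markov_stationary_gc(.markov_matrix(order, g, self_bias),
                                         order) - gc
  g <- stats::uniroot(f, c(0.02, 0.98), tol = 1e-9)$root
  .markov_matrix(order, g, self_bias)
}

# sample n bases; returns integer vector in 1..4 (A,C,G,T)
.sample_markov <- function(n, T_, order) {
  cum <- t(apply(T_, 1L, cumsum))
  u <- stats::runif(n)
  out <- integer(n)
  n_ctx <- nrow(T_)
  ctx <- sample.int(n_ctx, 1L)
  shift <- n_ctx %/% 4L
  for (i in seq_len(n)) {
    ui <- u[i]
    row <- cum[ctx, ]
    b <- 1L + (ui > row[1L]) + (ui > row[2L]) + (ui > row[3L])
    out[i] <- b
    if (order >= 1L) ctx <- ((ctx - 1L) %% shift) * 4L + b
  }
  out
}

.BASES <- c("A", "C", "G", "T")

# codon distribution: i.i.d. codons from a base composition, conditioned on
# excluding stop codons (table 11) and, optionally, cysteine codons; the
# composition is recalibrated so the conditional expected G+C equals gc
.codon_table <- function(gc, exclude_cys = TRUE) {
  codons <- as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))
  drop <- c("TAA", "TAG", "TGA", if (exclude_cys) c("TGT", "TGC"))
  codons <- setdiff(codons, drop)
  gc_cnt <- vapply(strsplit(codons, ""), function(x) sum(x %in% c("G", "C")),
                   0L)
  probs_for <- function(g) {
    p <- .base_probs(g)
    w <- vapply(strsplit(codons, ""), function(x) prod(p[x]), 0)
    w / sum(w)
  }
  f <- function(g) sum(probs_for(g) * gc_cnt) / 3 - gc
  g <- stats::uniroot(f, c(0.02, 0.98), tol = 1e-9)$root
  list(codons = codons, probs = probs_for(g))
}
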