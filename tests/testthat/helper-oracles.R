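# Independent brute-force oracles and small fixture builders.
# The oracles deliberately use plain loops over the printed formulas and
# never call the package's own implementations.

# weighted Pearson correlation by direct evaluation of the four
# weighted-moment formulas
bf_weighted_cor <- function(x, y, w) {
  n <- length(x)
  sw <- 0
  for (i in seq_len(n)) sw <- sw + w[i]
  xw <- 0; yw <- 0
  for (i in seq_len(n)) { xw <- xw + w[i] * x[i]; yw <- yw + w[i] * y[i] }
  xw <- xw / sw; yw <- yw / sw
  sx <- 0; sy <- 0
  for (i in seq_len(n)) {
    sx <- sx + w[i] * (x[i] - xw)^2
    sy <- sy + w[i] * (y[i] - yw)^2
  }
  sx <- sqrt(sx / sw); sy <- sqrt(sy / sw)
  acc <- 0
  for (i in seq_len(n))
    acc <- acc + w[i] * ((x[i] - xw) / sx) * ((y[i] - yw) / sy)
  acc / sw
}

bf_weights <- function(x, y, p = 1) {
  w <- numeric(length(x))
  for (i in seq_along(x)) w[i] <- max(x[i] / max(x), y[i] / max(y))^p
  w
}

bf_rw <- function(x, y, p = 1) bf_weighted_cor(x, y, bf_weights(x, y, p))

bf_rws <- function(x, y, sx, sy, p = 1) {
  w <- bf_weights(x, y, p)
  y2 <- y
  for (i in seq_along(y)) if (sx[i] * sy[i] < 0) y2[i] <- -y[i]
  bf_weighted_cor(x, y2, w)
}

bf_theta <- function(x, y, sx, sy, k = 30, T = 0.3, p = 1) {
  bf_rws(x, y, sx, sy, p) / (1 + exp(-k * (bf_rw(x, y, p) - T)))
}

# random association-pattern pair on a shared variant grid
random_pattern_pair <- function(n = 30, seed = 1) {
  set.seed(seed)
  v <- data.frame(variant_id = sprintf("v%03d", seq_len(n)), chrom = "1",
                  pos = seq(1e6, by = 1e4, length.out = n), ref = "A",
                  alt = "G", stringsAsFactors = FALSE)
  x <- stats::rexp(n, 1 / 2)
  y <- pmax(x * stats::runif(n, 0.5, 1.5) + stats::rnorm(n, 0, 0.5), 0)
  sx <- sample(c(-1L, 1L), n, replace = TRUE)
  sy <- ifelse(stats::runif(n) < 0.8, sx, -sx)
  sx[x == 0] <- 0L; sy[y == 0] <- 0L
  list(a = association_pattern(v, x, sx, trait = "a"),
       b = association_pattern(v, y, sy, trait = "b"),
       x = x, y = y, sx = sx, sy = sy)
}

# tiny polymorphic genotype matrix on one chromosome
toy_genotypes <- function(n = 100, m = 10, seed = 1, maf = 0.3) {
  set.seed(seed)
  d <- matrix(stats::rbinom(n * m, 2L, maf), n, m)
  genotype_matrix(d, data.frame(
    variant_id = sprintf("t%03d", seq_len(m)), chrom = "1",
    pos = seq(1e6, by = 5e4, length.out = m), ref = "A", alt = "G",
    stringsAsFactors = FALSE))
}

# two-variant haplotype-frequency r2 oracle: builds genotypes from known
# haplotype draws so the expected r2 is computable from first principles
hap_pair_genotypes <- function(n, p_ab, p_aB, p_Ab, p_bb, seed = 1) {
  set.seed(seed)
  haps <- matrix(c(1, 1, 1, 0, 0, 1, 0, 0), 4, 2, byrow = TRUE)
  draw <- function() haps[sample(4, n, replace = TRUE,
                                 prob = c(p_ab, p_aB, p_Ab, p_bb)), ]
  draw() + draw()
}
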