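# Independent brute-force oracles, deliberately written as plain double
# loops over the definition; they share no code with the package internals.

oracle_counts <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  cm <- 0L
  cm1 <- 0L
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      if (max(abs(x[i:(i + m - 1L)] - x[j:(j + m - 1L)])) <= r) {
        cm <- cm + 1L
        if (abs(x[i + m] - x[j + m]) <= r) cm1 <- cm1 + 1L
      }
    }
  }
  c(count_m = cm, count_m1 = cm1)
}

oracle_sampen <- function(x, m, r_coeff, r = NULL) {
  if (is.null(r))
    r <- max(r_coeff * sd(x), .Machine$double.eps * max(1, mean(abs(x))))
  cnt <- oracle_counts(x, m, r)
  if (any(cnt == 0)) return(NA_real_)
  -log(cnt[["count_m1"]] / cnt[["count_m"]])
}

# spectral-synthesis pink (1/f) noise, independent of the package generator
pink_noise <- function(n) {
  nf <- (n - 1L) %/% 2L
  coef <- complex(real = rnorm(nf), imaginary = rnorm(nf)) / sqrt(seq_len(nf))
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1L)] <- coef
  spec[n:(n - nf + 1L)] <- Conj(coef)
  x <- Re(fft(spec, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# split-plot sums of squares straight from the cell-mean definitions
oracle_split_plot <- function(d) {
  gm <- mean(d$y)
  n_cond <- length(unique(d$condition))
  subj_means <- tapply(d$y, d$subject, mean)
  subj_group <- tapply(as.character(d$group), d$subject, `[`, 1L)
  group_means <- tapply(d$y, d$group, mean)
  cond_means <- tapply(d$y, d$condition, mean)
  cell_means <- tapply(d$y, list(d$group, d$condition), mean)
  n_per_group <- table(subj_group)

  ss_subj <- n_cond * sum((subj_means - gm)^2)
  ss_group <- n_cond * sum(n_per_group * (group_means[names(n_per_group)] - gm)^2)
  ss_subj_within <- ss_subj - ss_group
  ss_cond <- sum(table(d$condition) * (cond_means - gm)^2)
  ss_cells <- 0
  for (g in rownames(cell_means)) for (cc in colnames(cell_means)) {
    ncell <- sum(d$group == g & d$condition == cc)
    ss_cells <- ss_cells + ncell * (cell_means[g, cc] - gm)^2
  }
  ss_int <- ss_cells - ss_group - ss_cond
  ss_tot <- sum((d$y - gm)^2)
  ss_resid <- ss_tot - ss_subj - ss_cond - ss_int
  list(group = ss_group, subj_within = ss_subj_within, cond = ss_cond,
       interaction = ss_int, resid = ss_resid)
}
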