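# Small fixtures and independent oracle implementations used across tests.

make_region_df <- function() {
  data.frame(
    id = 1:3, acronym = c("root", "A", "B"), name = c("Root", "Sub A", "Sub B"),
    parent = c(NA, "root", "root"), anatomical_group = "X",
    volume = c(1.0, 0.5, 0.25), stringsAsFactors = FALSE)
}

# acronyms for which upstream cell detection failed in the source dataset
failed_acronyms <- c("IF", "III", "SFO", "RH", "IAM", "IG", "MARN", "ACVII",
                     "VII", "SH", "ILA1", "AId6b", "AId6a", "AId5", "AId2/3",
                     "AId1")

single_group <- function(n = 7L) {
  data.frame(label = "g", n = as.integer(n), control = NA_character_,
             stringsAsFactors = FALSE)
}

three_groups <- function(n = 6L) {
  data.frame(label = c("ctrl", "trtA", "trtB"), n = rep(as.integer(n), 3),
             control = c(NA, "ctrl", "ctrl"), stringsAsFactors = FALSE)
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest down
  for (i in (m - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# textbook two-sample log-rank: sum over distinct event times of O - E in
# group a, variance by the hypergeometric formula
logrank_oracle <- function(ta, tb) {
  times <- sort(unique(c(ta, tb)))
  O <- E <- V <- 0
  for (tt in times) {
    na <- sum(ta >= tt); nb <- sum(tb >= tt); n <- na + nb
    da <- sum(ta == tt); db <- sum(tb == tt); d <- da + db
    if (n < 2) next
    O <- O + da
    E <- E + d * na / n
    V <- V + d * (na / n) * (nb / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}

# two-way ANOVA sums of squares from first principles (balanced design)
anova_oracle <- function(y, f1, f2) {
  gm <- mean(y)
  ss_total <- sum((y - gm)^2)
  m1 <- tapply(y, f1, mean); m2 <- tapply(y, f2, mean)
  m12 <- tapply(y, interaction(f1, f2), mean)
  n1 <- table(f1); n2 <- table(f2); n12 <- table(interaction(f1, f2))
  ss1 <- sum(n1 * (m1 - gm)^2)
  ss2 <- sum(n2 * (m2 - gm)^2)
  sscell <- sum(n12 * (m12 - gm)^2)
  ss12 <- sscell - ss1 - ss2
  ss_res <- ss_total - sscell
  df1 <- length(m1) - 1; df2 <- length(m2) - 1; df12 <- df1 * df2
  dfr <- length(y) - length(m12)
  list(F1 = (ss1 / df1) / (ss_res / dfr),
       F2 = (ss2 / df2) / (ss_res / dfr),
       F12 = (ss12 / df12) / (ss_res / dfr),
       ss = c(ss1, ss2, ss12, ss_res), df = c(df1, df2, df12, dfr))
}
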