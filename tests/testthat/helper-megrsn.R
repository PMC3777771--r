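# Shared fixtures and independent mini-oracles for the suite.

# direct one-line PLI formula (the independent oracle for pipeline PLI)
pli_formula <- function(phi_a, phi_b) abs(mean(sign(sin(phi_a - phi_b))))

# brute-force mean over the within-subset unordered pairs of a matrix
brute_subset_mean <- function(values, labels, subset) {
  idx <- match(subset, labels)
  tot <- 0; k <- 0
  for (i in seq_along(idx)) {
    for (j in seq_along(idx)) {
      if (i < j) { tot <- tot + values[idx[i], idx[j]]; k <- k + 1 }
    }
  }
  tot / k
}

# brute-force Benjamini-Hochberg step-up flags
brute_bh <- function(p, q = 0.05) {
  m <- length(p)
  ord <- order(p)
  passed <- p[ord] <= q * seq_len(m) / m
  k <- if (any(passed)) max(which(passed)) else 0
  flags <- logical(m)
  if (k > 0) flags[ord[seq_len(k)]] <- TRUE
  flags
}

# exhaustive 2^n enumeration of the Wilcoxon signed-rank two-sided p
brute_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  dev <- abs(w_obs - mu)
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    w <- sum(r[signs])
    if (abs(w - mu) >= dev - 1e-9) hits <- hits + 1
  }
  hits / 2^n
}

# pair-count enumeration of Kendall tau (tau-b)
brute_tau <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
    if (s > 0) C <- C + 1 else if (s < 0) D <- D + 1
  }
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# construct a pli_matrix directly (no signal processing)
make_matrix <- function(labels, values, band = "lower_alpha") {
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, roi_labels = labels,
                 band = megrsn::get_band(band), n_epochs_averaged = 1L),
            class = "pli_matrix")
}

const_matrix <- function(labels, value, band = "lower_alpha") {
  v <- matrix(value, length(labels), length(labels))
  diag(v) <- 0
  make_matrix(labels, v, band)
}

random_sym_matrix <- function(labels, band = "lower_alpha") {
  n <- length(labels)
  v <- matrix(0, n, n)
  v[upper.tri(v)] <- runif(n * (n - 1) / 2)
  v <- v + t(v)
  make_matrix(labels, v, band)
}

# small 4-network atlas drawn from the real registry (disjoint memberships)
mini_atlas <- function() {
  list(
    registry = c("Frontal_Med_Orb_L", "Frontal_Med_Orb_R", "Cingulum_Post_L",
                 "Cingulum_Post_R", "Precuneus_L", "Precuneus_R",
                 "Frontal_Mid_L", "Frontal_Inf_Tri_L", "Parietal_Inf_L",
                 "Angular_L",
                 "Frontal_Mid_R", "Frontal_Inf_Tri_R", "Parietal_Inf_R",
                 "Angular_R",
                 "Frontal_Sup_L", "Frontal_Sup_R", "Cingulum_Ant_L",
                 "Cingulum_Ant_R", "Supp_Motor_Area_L", "Supp_Motor_Area_R"),
    networks = list(
      DMN = c("Frontal_Med_Orb_L", "Frontal_Med_Orb_R", "Cingulum_Post_L",
              "Cingulum_Post_R", "Precuneus_L", "Precuneus_R"),
      FPN_left = c("Frontal_Mid_L", "Frontal_Inf_Tri_L", "Parietal_Inf_L",
                   "Angular_L"),
      FPN_right = c("Frontal_Mid_R", "Frontal_Inf_Tri_R", "Parietal_Inf_R",
                    "Angular_R"),
      ECN = c("Frontal_Sup_L", "Frontal_Sup_R", "Cingulum_Ant_L",
              "Cingulum_Ant_R", "Supp_Motor_Area_L", "Supp_Motor_Area_R")
    )
  )
}

# DMN-only atlas for null-calibration runs
dmn_atlas <- function() {
  a <- mini_atlas()
  list(registry = a$networks$DMN, networks = a$networks["DMN"])
}

# pipeline PLI of one generated pair (generation -> filter -> phase -> PLI)
pipeline_pair_pli <- function(spec, n, rate, seed) {
  ts <- generate_coupled_pair(spec, n, rate, seed)
  ep <- preprocess_recording(ts, band = spec$band, n_epochs = 1,
                             epoch_length = n)
  m <- pli_matrix(ep)
  m$values[1, 2]
}
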