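# Shared fixtures: all synthetic, built in code.

# Noiseless growth points of the default 9-point, 3-curve design.
exact_points <- function(E = 1.85, y0 = 0.009, D = 2) {
  des <- point_design(E = E, y0 = y0, D = D, sigma_y = 0)
  growth_points(des$layout$j, des$layout$x, des$exact, D = D)
}

# One seeded noisy replicate of the default design.
noisy_points <- function(seed, sigma_y = 2.4, E = 1.85, y0 = 0.009, D = 2) {
  des <- point_design(E = E, y0 = y0, D = D, sigma_y = sigma_y)
  sim_growth_points(simulate_points(des, n_sim = 1L, seed = seed), 1L)
}

# Tidy CSV for a small noiseless logistic series.
write_demo_csv <- function(path, n_wells = 3, n_cycles = 40,
                           y0 = 0.04, ymax = 600, E0 = 1.9, D = 2) {
  rows <- do.call(rbind, lapply(seq_len(n_wells) - 1L, function(j) {
    x <- seq_len(n_cycles)
    data.frame(well = paste0("W", j), dilution_exponent = j, cycle = x,
               fluorescence = logistic_model_value(y0 / D^j, ymax, E0, x))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(rows)
}

# Map an unordered pair (p, q) to its row in diffs$pairs.
pair_row <- function(diffs, p, q) {
  a <- min(p, q); b <- max(p, q)
  which(diffs$pairs$a == a & diffs$pairs$b == b)
}

# Random spanning chain over n points: consecutive pairs of a permutation.
random_spanning_rows <- function(diffs, seed) {
  set.seed(seed)
  perm <- sample(diffs$n_points)
  vapply(seq_len(diffs$n_points - 1L),
         function(k) pair_row(diffs, perm[k], perm[k + 1L]), integer(1))
}
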