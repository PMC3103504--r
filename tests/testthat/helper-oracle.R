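# Brute-force oracle for minimal-model steady states: sign changes of the
# right-hand side on a dense grid, refined by uniroot.
oracle_roots <- function(f_T, params, T_max = 20, n = 40001) {
  g <- function(T) params$beta_T - params$eps_T * T +
    f_T * T^2 / (params$theta_T^2 + T^2)
  grid <- seq(0, T_max, length.out = n)
  v <- g(grid)
  roots <- c()
  for (i in seq_len(n - 1)) {
    if (v[i] == 0) roots <- c(roots, grid[i])
    else if (v[i] * v[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(g, c(grid[i], grid[i + 1]),
                                       tol = 1e-12)$root)
    }
  }
  sort(unique(roots))
}

# Parameters whose activation drives vanish identically: every variable
# then relaxes to its basal level beta/eps.
zero_drive_params <- function() {
  detailed_params(k_1a = 0, k_1b = 0, k_1c = 0, k_2a = 0, k_2b = 0,
                  k_6 = 0, k_6b = 0, k_3 = 0, k_4a = 0, k_4b = 0,
                  k_5a = 0, k_5b = 0)
}

basal_state <- function(p) {
  c(T = p$beta_T / p$eps_T, R = p$beta_R / p$eps_R, M = p$beta_M / p$eps_M,
    delta = p$beta_delta / p$eps_delta, gamma = p$beta_gamma / p$eps_gamma,
    alpha = p$beta_alpha / p$eps_alpha)
}
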