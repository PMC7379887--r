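# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

toy_constant_model <- function() kinetic_model(2, 1, 0.5)

# Noise-free profile: means equal the solved trajectory, sd fixed.
exact_profile <- function(model, times = default_time_grid(), sd = 0.1,
                          include_synthesis = TRUE, n_replicates = 3) {
  traj <- solve_kinetics(model, times)
  species <- c("premature", "mature", if (include_synthesis) "synthesis")
  df <- purrr::map_dfr(species, function(sp) {
    tibble::tibble(time = times, species = sp, mean = traj[[sp]], sd = sd)
  })
  expression_profile(df, n_replicates = n_replicates)
}

# Independent fine-step RK4 integrator for the constant-rate system, used as
# an oracle for the closed-form solution (plain R, no shared code with the
# package's integrator).
rk4_constant <- function(k1, k2, k3, P0, M0, t_end, dt = 1e-3) {
  f <- function(y) c(k1 - k2 * y[1], k2 * y[1] - k3 * y[2])
  n <- ceiling(t_end / dt)
  dt <- t_end / n
  y <- c(P0, M0)
  for (i in seq_len(n)) {
    a <- f(y)
    b <- f(y + dt / 2 * a)
    c_ <- f(y + dt / 2 * b)
    d <- f(y + dt * c_)
    y <- y + dt / 6 * (a + 2 * b + 2 * c_ + d)
  }
  y
}

# constrained rate ranges used for identifiability-sensitive experiments:
# response timescales stay inside the 16 h observation window
experiment_ranges <- function() {
  list(k1 = c(0.5, 50), k2 = c(0.5, 8), k3 = c(0.2, 2))
}

max_rel_err <- function(x, ref) {
  max(abs(x - ref) / pmax(abs(ref), 1e-8 * max(abs(ref))))
}
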