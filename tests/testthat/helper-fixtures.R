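# Shared fixtures, built in code at load time (fast, deterministic).

# tiny hand-written table exercising parsing and grouping
toy_table <- function() {
  tree_data(data.frame(
    genotype_id = c("A", "A", "B"),
    p1 = c(1, 1, 0),
    dbh = c(2.5, 3.1, 4.0),
    h = c(2.0, 2.4, 3.0),
    cd = c(1.1, 1.3, 1.6),
    lh = c(2.1, 2.6, 3.2),
    lcd = c(1.0, 1.2, 1.5)
  ))
}

# noiseless power-law data: exact recovery oracle for the fixed fitters
noiseless_power_data <- function(n = 120, a1 = 1.2, b1 = 1.1, c1 = 0.3,
                                 seed = 7) {
  set.seed(seed)
  lh <- runif(n, 1.5, 9)
  lcd <- runif(n, 0.3, 4)
  tree_data(data.frame(
    genotype_id = rep(sprintf("G%02d", 1:6), length.out = n),
    p1 = rep(c(0, 1), length.out = n),
    dbh = a1 * lh^b1 * lcd^c1, h = NA, cd = NA, lh = lh, lcd = lcd))
}

# small simulated stand reused across NLME tests (one fit amortized)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_stand(sim_config(n_genotypes = 20L,
                                          trees_per_genotype = 15L,
                                          seed = 5L))
    }
    cache
  }
})

small_nlme_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- fit_nlme(small_sim()$data, model_form("power", "on_b"),
                         c("b1", "b2"), variance = "power")
    }
    cache
  }
})
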