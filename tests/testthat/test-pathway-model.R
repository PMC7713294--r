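test_that("build_network constructs the documented topology", {
  net <- build_network(4)
  expect_length(net$chain, 5)
  expect_length(net$complexes, 5)
  expect_identical(net$chain[1], "phytoene")
  expect_identical(net$chain[5], "lycopene")
  expect_identical(net$n_parameters, 14L)  # 5 k_f + 5 k_r + 4 k_cat

  minimal <- build_network(1)
  expect_length(minimal$chain, 2)
  expect_length(minimal$complexes, 2)

  ext <- build_network(6, extended = TRUE)
  expect_identical(ext$chain[7], "tetradehydrolycopene")
  expect_identical(
    carotene_species()$desaturation_index[
      carotene_species()$name == "tetradehydrolycopene"], 6L)
})

test_that("build_network validates its inputs", {
  expect_error(build_network(0), class = "carokin_invalid_network")
  expect_error(build_network(5), class = "carokin_invalid_network")
  expect_error(build_network(7, extended = TRUE),
               class = "carokin_invalid_network")
  expect_error(
    build_network(4, extended = TRUE,
                  branch_spec = data.frame(source = "didehydrolycopene",
                                           vmax = 1e-4, km = 5)),
    class = "carokin_unknown_species")
  expect_error(
    build_network(4, branch_spec = data.frame(source = "lycopene")),
    class = "carokin_invalid_network")
  # second-cyclisation source requires its precursor branch
  expect_error(
    build_network(4, extended = TRUE,
                  branch_spec = data.frame(source = "gamma_carotene",
                                           vmax = 1e-4, km = 5)),
    class = "carokin_unknown_species")
  ok <- build_network(4, extended = TRUE,
                      branch_spec = data.frame(
                        source = c("lycopene", "gamma_carotene"),
                        vmax = 1e-4, km = 5))
  expect_identical(ok$branches$product, c("gamma_carotene", "beta_carotene"))
})

test_that("species metadata satisfies the chain invariants", {
  tab <- carotene_species()
  chain <- tab[tab$cycle_count == 0, ]
  expect_identical(chain$desaturation_index, 0:6)
  expect_identical(chain$name[1], "phytoene")
  expect_true(all(tab$cycle_count %in% 0:2))
  # cyclisation edges preserve desaturation count and add one ring
  edges <- cyclisation_edges()
  for (i in seq_len(nrow(edges))) {
    s <- tab[tab$name == edges$source[i], ]
    p <- tab[tab$name == edges$product[i], ]
    expect_identical(p$desaturation_index, s$desaturation_index)
    expect_identical(p$cycle_count, s$cycle_count + 1L)
  }
})

test_that("rhs matches the independent reference implementation", {
  withr::local_seed(11)
  nets <- list(build_network(1), build_network(4),
               build_network(5, extended = TRUE,
                             branch_spec = data.frame(
                               source = c("lycopene", "neurosporene"),
                               vmax = c(2e-4, 1e-4), km = 5)))
  for (net in nets) {
    n <- net$n_steps
    for (rep in 1:10) {
      p <- draw_parameters(net)
      st <- random_state(net)
      expect_equal(network_rhs(st, p, net, influx = 0.01),
                   reference_rhs(st, p, net, influx = 0.01),
                   tolerance = 1e-12)
    }
  }
})

test_that("rhs special cases behave as stated", {
  net <- build_network(4)
  zero <- kinetic_parameters(rep(0, 5), rep(0, 5), rep(0, 4))
  st <- random_state(net)
  expect_true(all(network_rhs(st, zero, net) == 0))

  # single active flux at t = 0
  p <- fast_params()
  assay <- preset_assay("dense_schedule")
  y0 <- initial_state(net, assay)
  dy <- network_rhs(y0, p, net)
  v0 <- p$k_f[1] * assay$enzyme_total * 10
  expect_equal(dy[["ES_phytoene"]], v0)
  expect_equal(dy[["phytoene"]], -v0)
  expect_equal(dy[["E"]], -v0)
  others <- setdiff(names(dy), c("ES_phytoene", "phytoene", "E"))
  expect_true(all(dy[others] == 0))

  expect_error(network_rhs(y0[-1], p, net), class = "carokin_shape_error")
  y0neg <- y0; y0neg[1] <- -1
  expect_error(network_rhs(y0neg, p, net), class = "carokin_domain_error")
})

test_that("stoichiometric closure holds for any state and parameters", {
  withr::local_seed(21)
  net <- build_network(5, extended = TRUE,
                       branch_spec = data.frame(
                         source = c("lycopene", "gamma_carotene"),
                         vmax = 1e-4, km = 2))
  n <- net$n_steps
  enzyme_cols <- c("E", net$complexes)
  carotene_cols <- setdiff(net$state_names, "E")
  for (rep in 1:25) {
    p <- draw_parameters(net)
    dy <- network_rhs(random_state(net), p, net)
    scale <- max(abs(dy))
    expect_lt(abs(sum(dy[carotene_cols])), 1e-13 * max(scale, 1))
    expect_lt(abs(sum(dy[enzyme_cols])), 1e-13 * max(scale, 1))
  }
})

test_that("enzyme-involving fluxes are linear in the enzyme species", {
  withr::local_seed(31)
  net <- build_network(4)
  p <- draw_parameters(net)
  st <- random_state(net)
  st2 <- st
  st2[c("E", net$complexes)] <- 2 * st2[c("E", net$complexes)]
  dy1 <- network_rhs(st, p, net)
  dy2 <- network_rhs(st2, p, net)
  # doubling E and all complexes doubles every enzyme-involving flux
  expect_equal(dy2[["E"]], 2 * dy1[["E"]], tolerance = 1e-12)
  expect_equal(unname(dy2[net$complexes]), 2 * unname(dy1[net$complexes]),
               tolerance = 1e-12)
})

test_that("analytic Jacobian agrees with finite differences", {
  withr::local_seed(41)
  net <- build_network(4, extended = FALSE)
  p <- draw_parameters(net)
  st <- random_state(net)
  a <- carokin:::network_cpp_args(net, 0)
  J <- carokin:::crti_jacobian_cpp(as.numeric(st), a$n_steps, p$k_f, p$k_r,
                                   p$k_cat, a$bsrc, a$bdst, a$bvmax, a$bkm,
                                   0, 0L)
  h <- 1e-6
  for (j in seq_along(st)) {
    stp <- st; stp[j] <- stp[j] + h
    stm <- st; stm[j] <- stm[j] - h
    num <- (network_rhs(stp, p, net) - network_rhs(stm, p, net)) / (2 * h)
    expect_equal(unname(J[, j]), unname(num), tolerance = 1e-6)
  }
})

test_that("conservation_residuals handles trivial and error cases", {
  net <- build_network(4)
  st <- random_state(net)
  traj <- rbind(st, st, st)
  expect_equal(unname(conservation_residuals(traj, net)), c(0, 0))
  zero <- matrix(0, nrow = 2, ncol = length(net$state_names))
  expect_error(conservation_residuals(zero, net),
               class = "carokin_undefined_ratio")
  expect_error(conservation_residuals(traj[, -1], net),
               class = "carokin_shape_error")
})

test_that("kinetic_parameters validates shapes and domain", {
  expect_error(kinetic_parameters(rep(1, 4), rep(1, 5), rep(0.1, 4)),
               class = "carokin_shape_error")
  expect_error(kinetic_parameters(rep(1, 5), rep(1, 5), c(rep(0.1, 3), -1)),
               class = "carokin_domain_error")
  p <- kinetic_parameters(rep(1, 5), rep(1, 5), rep(0.1, 4))
  expect_s3_class(p, "kinetic_params")
})

test_that("network summary lists every reaction", {
  net <- build_network(4)
  txt <- network_summary(net)
  expect_length(txt, 5 + 4)  # 5 binding equilibria + 4 catalytic steps
  expect_true(any(grepl("dead end|ES_lycopene", txt)) ||
              any(grepl("ES_lycopene", txt)))
  expect_false(any(grepl("ES_lycopene -> E \\+", txt)))  # no terminal catalysis
})
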