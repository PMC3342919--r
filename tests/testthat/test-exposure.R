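two_shed_net <- function() {
  watershed_network(data.frame(
    shed_id = 1:2, area_acres = c(100, 100), downstream_id = c(NA, NA),
    seed_x = c(2.5, 7.5), seed_y = c(5, 5)))
}

test_that("grid cells land in exactly one intersection; population conserved", {
  net <- two_shed_net()
  cty <- data.frame(county_id = 1:2, seed_x = c(5, 5), seed_y = c(2.5, 7.5),
                    uic_code = c(1L, 8L))
  # 2x2 grid of 5 km cells split by both boundaries
  grid <- data.frame(cell_id = 1:4,
                     x = c(2.5, 7.5, 2.5, 7.5), y = c(2.5, 2.5, 7.5, 7.5),
                     pop = c(10, 20, 30, 40))
  pops <- intersect_population(grid, net, cty)
  expect_equal(sum(pops$pop), 100)
  # hand assignment: cell 1 -> shed1/county1, 2 -> shed2/county1, etc.
  expect_equal(pops$pop[pops$shed_id == 1 & pops$county_id == 1], 10)
  expect_equal(pops$pop[pops$shed_id == 2 & pops$county_id == 1], 20)
  expect_equal(pops$pop[pops$shed_id == 1 & pops$county_id == 2], 30)
  expect_equal(pops$pop[pops$shed_id == 2 & pops$county_id == 2], 40)
})

test_that("county exposure is the population-weighted mean of shed scores", {
  pops <- data.frame(shed_id = c(1L, 2L), county_id = c(1L, 1L),
                     pop = c(25, 75))
  got <- county_exposure(c("1" = 2, "2" = 6), pops)
  expect_equal(got$exposure, 5)           # (2*25 + 6*75) / 100
  expect_equal(got$log_exposure, log1p(5))
  solo <- county_exposure(c("1" = 7), data.frame(shed_id = 1L, county_id = 1L,
                                                 pop = 50))
  expect_equal(solo$exposure, 7)
  expect_error(county_exposure(c("1" = 1), pops), "missing score")
})

test_that("a county is scored by where its people live, not its releases", {
  # the extreme case: one county split between two watersheds, all releases
  # in watershed 1 but every resident in watershed 2
  pops <- data.frame(shed_id = c(1L, 2L), county_id = c(1L, 1L),
                     pop = c(0, 1000))
  scores <- c("1" = 500, "2" = 0.25)
  expect_equal(county_exposure(scores, pops)$exposure, 0.25)
})

test_that("exposure is convex and invariant to uniform population scaling", {
  set.seed(31)
  for (rep in 1:5) {
    n_shed <- sample(3:8, 1); n_cty <- sample(2:5, 1)
    pops <- expand.grid(shed_id = seq_len(n_shed), county_id = seq_len(n_cty))
    pops$pop <- rpois(nrow(pops), 40)
    sc <- setNames(runif(n_shed, 0, 50), seq_len(n_shed))
    got <- county_exposure(sc, pops)
    for (c_ in got$county_id) {
      contrib <- pops$shed_id[pops$county_id == c_ & pops$pop > 0]
      if (!length(contrib)) next
      expect_gte(got$exposure[got$county_id == c_] + 1e-12, min(sc[contrib]))
      expect_lte(got$exposure[got$county_id == c_] - 1e-12, max(sc[contrib]))
    }
    scaled <- pops; scaled$pop <- scaled$pop * 17
    expect_equal(county_exposure(sc, scaled)$exposure, got$exposure)
  }
})

test_that("zero-population counties are flagged with undefined exposure", {
  pops <- data.frame(shed_id = c(1L, 1L), county_id = c(1L, 2L),
                     pop = c(10, 0))
  got <- county_exposure(c("1" = 3), pops)
  expect_true(got$zero_pop[got$county_id == 2])
  expect_true(is.na(got$exposure[got$county_id == 2]))
})

test_that("with no upstream links the area variant equals onsite rho/area", {
  net <- two_shed_net()
  sums <- data.frame(shed_id = c(1L, 2L),
                     chemical_name = c("Lead", "Benzene"),
                     release_kg_yr = c(10, 4))
  pops <- data.frame(shed_id = c(1L, 2L), county_id = c(1L, 1L),
                     pop = c(30, 70))
  tab <- build_exposure_table(sums, net, pops)
  rho <- c(0, 4 * 55000)                     # carcinogen class, weighted
  expect_equal(tab$carcinogen_tox_onsite,
               sum(rho * c(30, 70)) / 100)
  expect_equal(tab$carcinogen_tox_area,
               sum(rho / 100 * c(30, 70)) / 100)  # pi = rho / area_s
  expect_equal(tab$log_carcinogen_tox_area, log1p(tab$carcinogen_tox_area))
})

test_that("pipeline intersections conserve the grid population", {
  for (seed in c(2, 9)) {
    cfg <- small_config(seed = seed)
    g <- generate_population_grid(cfg)
    pops <- intersect_population(g, generate_watershed_network(cfg),
                                 generate_counties(cfg))
    expect_equal(sum(pops$pop), attr(g, "total_pop"))
  }
})
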