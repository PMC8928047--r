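test_that("exact queries read simple chain CPTs", {
  net <- chain_ab(0.9)
  expect_equal(exact_query(net, "b", "1", list(a = "1")), 0.9)
  expect_equal(exact_query(net, "b", "0", list(a = "1")), 0.1)
  # complements sum to one under any evidence
  expect_equal(exact_query(net, "b", c("0", "1"), list(a = "0")), 1)
})

test_that("exact marginals match the independent joint enumerator", {
  for (s in 1:10) {
    net <- random_discrete_network(5, seed = s + 40)
    v <- net$dag$nodes[1 + (s %% 5)]
    lev <- net$levels[[v]][1]
    expect_equal(exact_query(net, v, lev),
                 oracle_conditional(net, v, lev, list()), tolerance = 1e-12)
    # and one conditional with a single evidence node
    others <- setdiff(net$dag$nodes, v)
    ev_node <- others[1 + (s %% length(others))]
    ev <- setNames(list(net$levels[[ev_node]][1]), ev_node)
    expect_equal(exact_query(net, v, lev, ev),
                 oracle_conditional(net, v, lev, ev), tolerance = 1e-12)
  }
})

test_that("evidence already implied by existing evidence changes nothing", {
  # a -> b deterministic, b -> c noisy: conditioning on the implied b = 1 on
  # top of a = 1 must leave P(c | evidence) untouched
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  net <- ground_truth_network(g, list(
    a = array(c(0.4, 0.6), 2, dimnames = list(a = c("0", "1"))),
    b = array(c(1, 0, 0, 1), c(2, 2),
              dimnames = list(b = c("0", "1"), a = c("0", "1"))),
    c = array(c(0.8, 0.2, 0.3, 0.7), c(2, 2),
              dimnames = list(c = c("0", "1"), b = c("0", "1")))))
  p1 <- exact_query(net, "c", "1", list(a = "1"))
  p2 <- exact_query(net, "c", "1", list(a = "1", b = "1"))
  expect_equal(p1, p2, tolerance = 1e-12)
  expect_equal(p1, 0.7)
})

test_that("zero-probability evidence is an explicit error", {
  # b is a deterministic copy of a, so evidence {a = 1, b = 0} is impossible
  g <- dag(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  net <- ground_truth_network(g, list(
    a = array(c(0.4, 0.6), 2, dimnames = list(a = c("0", "1"))),
    b = array(c(1, 0, 0, 1), c(2, 2),
              dimnames = list(b = c("0", "1"), a = c("0", "1"))),
    c = array(c(0.8, 0.2, 0.3, 0.7), c(2, 2),
              dimnames = list(c = c("0", "1"), b = c("0", "1")))))
  expect_error(exact_query(net, "c", "1", list(a = "1", b = "0")),
               "undefined")
  expect_error(lw_query(net, "c", "1", list(a = "1", b = "0"),
                        n_samples = 500, seed = 1), "degenerate")
})

test_that("likelihood weighting agrees with enumeration", {
  worst <- 0
  for (s in 1:10) {
    net <- random_discrete_network(5, seed = s + 60)
    v <- net$dag$nodes[2]
    lev <- net$levels[[v]][1]
    others <- setdiff(net$dag$nodes, v)
    ev <- setNames(list(net$levels[[others[1]]][1]), others[1])
    ex <- exact_query(net, v, lev, ev)
    lw <- lw_query(net, v, lev, ev, n_samples = 1e5, seed = s)
    worst <- max(worst, abs(lw - ex))
  }
  expect_lt(worst, 0.01)
})

test_that("likelihood weighting is deterministic given its seed", {
  net <- cardiometabolic_network()
  q <- function(seed) lw_query(net, "risk", "high",
                               list(mets = "MU", bmi = "obese"),
                               n_samples = 20000, seed = seed)
  expect_identical(q(5), q(5))
  expect_false(identical(q(5), q(6)))
})

test_that("a sure event is estimated as exactly one", {
  net <- chain_ab(1.0)
  expect_equal(lw_query(net, "b", c("0", "1"), n_samples = 1000, seed = 1), 1)
  res <- query_ci(net, "b", c("0", "1"), replicates = 5, n_samples = 1000)
  expect_equal(res$point, 1)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
})

test_that("confidence intervals are ordered, cover the exact value, and shrink", {
  net <- cardiometabolic_network()
  ev <- list(mets = "MU", bmi = "obese")
  ex <- exact_query(net, "risk", "high", ev)
  covered <- 0
  for (s in 1:20) {
    ci <- query_ci(net, "risk", "high", ev, replicates = 10,
                   n_samples = 2000, seed = s)
    expect_true(ci$ci_low <= ci$point && ci$point <= ci$ci_high)
    if (ci$ci_low <= ex && ex <= ci$ci_high) covered <- covered + 1
  }
  expect_gte(covered, 18)
  # Monte Carlo error scaling: the wide-sample CI is narrower most of the time
  narrower <- 0
  for (s in 1:10) {
    w1 <- with(query_ci(net, "risk", "high", ev, replicates = 8,
                        n_samples = 10000, seed = s), ci_high - ci_low)
    w2 <- with(query_ci(net, "risk", "high", ev, replicates = 8,
                        n_samples = 40000, seed = s + 100), ci_high - ci_low)
    if (w2 < w1) narrower <- narrower + 1
  }
  expect_gte(narrower, 8)
})

test_that("the bootstrap CI mode refits CPTs per resample", {
  net <- cardiometabolic_network()
  d <- generate_from_network(net, 2000, seed = 30)
  fit <- fit_cpts(net$dag, d)
  res <- query_ci(fit, "risk", "high", list(mets = "MU"), replicates = 8,
                  n_samples = 4000, seed = 2, method = "bootstrap", data = d)
  expect_true(res$ci_low < res$ci_high)
  expect_error(query_ci(fit, "risk", "high", list(), replicates = 4,
                        method = "bootstrap"), "data")
})

test_that("the reasoning report sweeps scenarios and normalises", {
  net <- cardiometabolic_network()
  rep0 <- reasoning_report(net, list(), outcome = "risk")
  expect_equal(nrow(rep0), 0)
  scen <- list(old = list(age = "65-74"), young = list(age = "30-49"))
  rep <- reasoning_report(net, scen, outcome = "risk", replicates = 5,
                          n_samples = 4000, seed = 3)
  expect_equal(nrow(rep), 6)
  for (s in names(scen)) {
    tot <- sum(rep$point[rep$scenario == s])
    expect_lt(abs(tot - 1), 0.02)
  }
  # qualitative age gradient: high risk rises with age
  expect_gt(rep$point[rep$scenario == "old" & rep$category == "high"],
            rep$point[rep$scenario == "young" & rep$category == "high"])
})

test_that("query validation names the offending node or level", {
  net <- chain_ab()
  expect_error(exact_query(net, "z", "1"), "unknown node")
  expect_error(exact_query(net, "b", "9"), "unknown level")
  expect_error(exact_query(net, "b", "1", list(b = "1")), "event node")
  expect_error(lw_query(net, "b", "1", list(q = "1")), "unknown node")
})
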