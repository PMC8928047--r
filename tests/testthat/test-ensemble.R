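test_that("strength and direction frequencies are exact counts", {
  nodes <- c("u", "v", "w")
  # 300 replicates: edge u-v in 150, of which 90 oriented u -> v
  dags <- c(replicate(90, dag(nodes, rbind(c("u", "v"))), simplify = FALSE),
            replicate(60, dag(nodes, rbind(c("v", "u"))), simplify = FALSE),
            replicate(150, dag(nodes), simplify = FALSE))
  ast <- arc_strengths(dags)
  uv <- ast[ast$from == "u" & ast$to == "v", ]
  expect_equal(uv$strength, 0.5)
  expect_equal(uv$direction, 0.6)
  vu <- ast[ast$from == "v" & ast$to == "u", ]
  expect_equal(vu$strength, 0.5)
  expect_equal(vu$direction, 0.4)
  expect_equal(attr(ast, "B"), 300)
})

test_that("strength table agrees with a brute-force recount", {
  set.seed(21)
  nodes <- paste0("n", 1:5)
  dags <- lapply(1:40, function(i) {
    k <- sample(0:4, 1)
    g <- dag(nodes)
    for (j in seq_len(k)) {
      uv <- sample(nodes, 2)
      cand <- tryCatch(dag(nodes, unique(rbind(g$arcs, uv))),
                       error = function(e) NULL)
      if (!is.null(cand)) g <- cand
    }
    g
  })
  ast <- arc_strengths(dags)
  for (i in seq_len(nrow(ast))) {
    u <- ast$from[i]; v <- ast$to[i]
    n_uv <- sum(vapply(dags, function(g)
      any(g$arcs[, 1] == u & g$arcs[, 2] == v), logical(1)))
    n_vu <- sum(vapply(dags, function(g)
      any(g$arcs[, 1] == v & g$arcs[, 2] == u), logical(1)))
    expect_equal(ast$strength[i], (n_uv + n_vu) / 40)
    expect_equal(ast$direction[i], n_uv / (n_uv + n_vu))
  }
  # direction frequencies are proper wherever an edge exists
  key <- paste(pmin(ast$from, ast$to), pmax(ast$from, ast$to))
  for (k in unique(key)) {
    expect_equal(sum(ast$direction[key == k]), 1)
  }
})

test_that("bootstrap learning is deterministic and honours the whitelist", {
  net <- cardiometabolic_network()
  d <- generate_from_network(net, 800, seed = 6)
  cons <- arc_constraints(d$nodes, whitelist = rbind(c("age", "risk")))
  dags1 <- bootstrap_learn(d, 10, cons, seed = 9)
  dags2 <- bootstrap_learn(d, 10, cons, seed = 9)
  expect_identical(lapply(dags1, `[[`, "arcs"), lapply(dags2, `[[`, "arcs"))
  ast <- arc_strengths(dags1)
  expect_equal(ast$strength[ast$from == "age" & ast$to == "risk"], 1)
  expect_equal(ast$direction[ast$from == "age" & ast$to == "risk"], 1)
})

test_that("B = 1 without resampling reduces to a single tabu search", {
  d <- generate_from_network(chain_ab(0.9), 500, seed = 7)
  one <- bootstrap_learn(d, 1, resample = FALSE, seed = 1)
  direct <- tabu_search(d)
  expect_identical(one[[1]]$arcs, direct$arcs)
})

test_that("thresholding keeps, drops and nests edges as specified", {
  nodes <- c("u", "v", "w")
  tab <- arc_strength_table(
    data.frame(from = c("u", "v", "v", "w"), to = c("v", "u", "w", "v"),
               strength = c(0.5, 0.5, 0.85, 0.85),
               direction = c(0.6, 0.4, 0.9, 0.1)), nodes, 100)
  g_half <- averaged_network(tab, 0.5)
  expect_true(amat(g_half)["u", "v"])   # >= 0.5 retained, majority u -> v
  expect_true(amat(g_half)["v", "w"])
  g_strict <- averaged_network(tab, 0.85, strict = TRUE)
  expect_equal(nrow(g_strict$arcs), 0)  # strength 0.85 dropped under "> 0.85"
  expect_equal(nrow(averaged_network(tab, 1.01)$arcs), 0)
  # monotone nesting across thresholds
  key <- function(g) paste(g$arcs[, 1], g$arcs[, 2])
  for (t2 in c(0.6, 0.86, 0.99)) {
    expect_true(all(key(averaged_network(tab, t2)) %in% key(g_half)))
  }
})

test_that("a consensus cycle is repaired by dropping the weakest arc, loudly", {
  nodes <- c("u", "v", "w")
  tab <- arc_strength_table(
    data.frame(from = c("u", "v", "w"), to = c("v", "w", "u"),
               strength = c(0.9, 0.8, 0.7), direction = c(1, 1, 1)),
    nodes, 100)
  expect_warning(g <- averaged_network(tab, 0.5), "cycle")
  m <- amat(g)
  expect_true(m["u", "v"] && m["v", "w"])
  expect_false(m["w", "u"])
})

test_that("mismatched node sets are rejected", {
  expect_error(arc_strengths(list(dag(c("a", "b")), dag(c("a", "c")))),
               "node set")
})
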