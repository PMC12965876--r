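make_presence_fixture <- function(n = 80, seed = 40) {
  set.seed(seed)
  env <- data.frame(site_id = sprintf("s%03d", 1:n),
                    clay = rnorm(n), mat = rnorm(n))
  conc <- matrix(0, n, 2, dimnames = list(env$site_id, c("pa", "pb")))
  conc[sample(n, n / 2), "pa"] <- 0.05
  conc[sample(n, 10), "pb"] <- 0.02
  model <- structure(list(groups = list(pesticides = c("pa", "pb"),
                                        soil = "clay", climate = "mat",
                                        ecosystem = character(0))),
                     class = "driver_glm")
  list(env = env, conc = conc, models = list(metric1 = model))
}

test_that("presence/absence tests pair retained pesticides with model environment", {
  fx <- make_presence_fixture()
  res <- presence_env_tests(fx$models, fx$conc, fx$env)
  expect_equal(nrow(res), 4L)  # 2 pesticides x 2 env vars
  expect_true(all(res$n_present + res$n_absent == nrow(fx$env)))
  expect_true(all(res$q >= res$p, na.rm = TRUE))

  # identical env values in both groups: H = 0, p = 1
  fx$env$clay <- 1
  res0 <- presence_env_tests(fx$models, fx$conc, fx$env)
  r <- res0[res0$env_var == "clay" & res0$pesticide == "pa", ]
  expect_equal(r$H, 0)
  expect_equal(r$p, 1)

  # a pesticide detected everywhere is skipped with a reason
  fx2 <- make_presence_fixture()
  fx2$conc[, "pa"] <- 0.05
  res2 <- presence_env_tests(fx2$models, fx2$conc, fx2$env)
  expect_true(all(is.na(res2$H[res2$pesticide == "pa"])))
  expect_match(res2$skipped[res2$pesticide == "pa"][1], "empty presence group")
})

test_that("two-group Kruskal-Wallis equals the squared standardized rank-sum statistic", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    x <- sample(1:8, n, replace = TRUE)  # integer data to force ties
    g <- factor(sample(c("p", "a"), n, replace = TRUE, prob = c(0.5, 0.5)))
    if (nlevels(droplevels(g)) < 2) next
    H <- kruskal.test(x, g)$statistic
    if (length(unique(x)) == 1) next
    expect_equal(unname(H), ranksum_z2(x, g), tolerance = 1e-10)
  }
  # hand computation: (1,2,3) vs (10,11,12), no ties
  H <- kruskal.test(c(1, 2, 3, 10, 11, 12),
                    factor(rep(c("a", "b"), each = 3)))$statistic
  expect_equal(unname(H), 3.857, tolerance = 1e-3)
})

test_that("Kruskal-Wallis H is invariant under strictly monotone transforms", {
  set.seed(42)
  x <- rlnorm(30)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  H1 <- kruskal.test(x, g)$statistic
  expect_equal(unname(kruskal.test(log(x), g)$statistic), unname(H1), tolerance = 1e-12)
  expect_equal(unname(kruskal.test(x^3, g)$statistic), unname(H1), tolerance = 1e-12)
})

test_that("Spearman screen captures perfect monotone association and rank invariance", {
  set.seed(43)
  n <- 50
  agg <- data.frame(site_id = sprintf("s%02d", 1:n),
                    n_detected = sample(0:12, n, replace = TRUE))
  biodiv <- data.frame(site_id = agg$site_id,
                       inc = rank(agg$n_detected, ties.method = "average") + 0,
                       noise = rnorm(n),
                       const = 1)
  res <- spearman_screen(biodiv, agg)
  expect_equal(res$rho[res$metric == "inc"], 1, tolerance = 1e-12)
  expect_true(is.na(res$rho[res$metric == "const"]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))

  # invariance under a strictly monotone transform of either variable
  biodiv2 <- biodiv
  biodiv2$noise <- exp(biodiv2$noise)
  res2 <- spearman_screen(biodiv2, agg)
  expect_equal(res2$rho[res2$metric == "noise"],
               res$rho[res$metric == "noise"], tolerance = 1e-12)

  # too few complete pairs reported, not computed
  biodiv3 <- biodiv[1:3, ]
  res3 <- spearman_screen(biodiv3, agg[1:3, ])
  expect_true(all(is.na(res3$rho)))
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(44)
  p <- runif(40)^2
  q <- p.adjust(p, "BH")
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # ordering preserved
})

test_that("ecosystem residue comparison separates disjoint supports with distinct letters", {
  set.seed(45)
  n <- 40
  env <- data.frame(site_id = sprintf("s%02d", 1:n),
                    ecosystem = rep(c("annual_cropland", "extensive_grassland"), each = 20))
  conc <- matrix(0, n, 15, dimnames = list(env$site_id, sprintf("p%02d", 1:15)))
  # croplands: 10-15 residues; grasslands: 0-2 -> disjoint count supports
  for (i in 1:20) conc[i, sample(15, sample(10:15, 1))] <- 0.05
  for (i in 21:40) conc[i, sample(15, sample(0:2, 1))] <- 0.05
  res <- ecosystem_residue_comparison(conc, env)
  expect_lt(res$pairs$q, 0.001)
  expect_true(res$letters["annual_cropland"] != res$letters["extensive_grassland"])

  # one distribution -> shared letter and q above alpha in most draws
  conc2 <- matrix(rbinom(n * 15, 1, 0.3) * 0.05, n,
                  dimnames = list(env$site_id, sprintf("p%02d", 1:15)))
  res2 <- ecosystem_residue_comparison(conc2, env)
  expect_true(all(res2$pairs$q >= res2$pairs$p))

  env1 <- env; env1$ecosystem <- "annual_cropland"
  expect_error(ecosystem_residue_comparison(conc, env1), ">= 2 ecosystem")
})

test_that("compact letter display shares a letter exactly when a pair is not significant", {
  groups <- c("A", "B", "C")
  pairs <- data.frame(g1 = c("A", "A", "B"), g2 = c("B", "C", "C"))
  share <- function(l, a, b) {
    any(strsplit(l[[a]], "")[[1]] %in% strsplit(l[[b]], "")[[1]])
  }
  # only A-C significant: A and C must differ, both may share with B
  l1 <- compact_letter_display(groups, pairs$g1, pairs$g2, c(FALSE, TRUE, FALSE))
  expect_false(share(l1, "A", "C"))
  expect_true(share(l1, "A", "B"))
  expect_true(share(l1, "B", "C"))
  # all significant: three distinct letters
  l2 <- compact_letter_display(groups, pairs$g1, pairs$g2, rep(TRUE, 3))
  expect_false(share(l2, "A", "B") || share(l2, "A", "C") || share(l2, "B", "C"))
  # none significant: everyone shares one letter
  l3 <- compact_letter_display(groups, pairs$g1, pairs$g2, rep(FALSE, 3))
  expect_true(share(l3, "A", "B") && share(l3, "A", "C"))
})
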