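test_that("plug-in ICC follows the shared-over-total variance ratio", {
  expect_equal(icc_plugin(0.5, 0.3, 0.2, 0), 1)
  expect_equal(icc_plugin(1, 1, 1, 1), 0.75)
  expect_equal(icc_plugin(0.60, 0.44, 0.64, 0.60), 1.68 / 2.28)
  expect_warning(v <- icc_plugin(0, 0, 0, 0), "degenerate")
  expect_equal(v, 1)
})

test_that("ICC is monotone in its components", {
  base <- icc_plugin(0.6, 0.4, 0.6, 1.0)
  expect_lt(icc_plugin(0.6, 0.4, 0.6, 1.5), base)   # decreasing in js
  expect_gt(icc_plugin(0.9, 0.4, 0.6, 1.0), base)   # increasing in t
  grid <- seq(0.1, 5, by = 0.1)
  expect_true(all(diff(icc_plugin(0.6, 0.4, 0.6, grid)) < 0))
})

test_that("posterior ICC table summarises per-draw ratios per group", {
  idx <- species_stream_index(c("A", "B"), c("X", "Y"))
  nm <- c("sigma2_t", sprintf("sigma2_j[%s]", c("A", "B")),
          sprintf("sigma2_s[%s]", c("X", "Y")),
          sprintf("sigma2_js[%s,%s]", idx$groups$species,
                  idx$groups$stream))
  set.seed(3)
  d <- matrix(rexp(200 * length(nm), 2), 200, length(nm),
              dimnames = list(NULL, nm))
  attr(d, "index") <- idx
  tab <- compute_icc(d)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$icc_mean >= 0 & tab$icc_mean <= 1))
  expect_true(all(tab$icc_lower <= tab$icc_mean &
                    tab$icc_mean <= tab$icc_upper))
  # manual check for one group
  g <- 3  # species A, stream Y
  manual <- (d[, "sigma2_t"] + d[, "sigma2_j[A]"] + d[, "sigma2_s[Y]"]) /
    (d[, "sigma2_t"] + d[, "sigma2_j[A]"] + d[, "sigma2_s[Y]"] +
       d[, "sigma2_js[A,Y]"])
  expect_equal(tab$icc_mean[g], mean(manual))
  expect_equal(tab$icc_lower[g], unname(quantile(manual, 0.025)))
  # plug-in of the means differs from the mean of ratios but both lie in
  # the credible interval
  expect_true(tab$icc_plugin[g] >= tab$icc_lower[g] &&
                tab$icc_plugin[g] <= tab$icc_upper[g])
})

test_that("covariate variance is beta^2 times the covariate variance", {
  x <- c(-1, 0, 1)
  expect_equal(covariate_variance(0, x), 0)
  expect_equal(covariate_variance(2, x), 4)
  expect_equal(covariate_variance(c(1, -3), rep(0.7, 10)), c(0, 0))
  # matches an explicit per-draw sample variance
  set.seed(8)
  b <- rnorm(50); xx <- rnorm(14)
  expect_equal(covariate_variance(b, xx),
               vapply(b, function(bb) var(bb * xx), numeric(1)))
  # divisor option
  expect_equal(covariate_variance(2, x, divisor = "n"),
               var(2 * x) * 2 / 3)
})

test_that("synchrony proportion averages per-draw ratios", {
  expect_equal(synchrony_proportion(rep(2, 100), rep(2, 100))
               $proportion$mean, 0.5)
  expect_equal(synchrony_proportion(rep(0, 100), runif(100))
               $proportion$mean, 0)
  r <- synchrony_proportion(c(1, 3), c(1, 1))
  expect_equal(r$proportion_draws, c(0.5, 0.75))
  expect_equal(r$proportion$mean, 0.625)
  expect_warning(z <- synchrony_proportion(c(0, 1), c(0, 1)), "zero")
  expect_equal(z$proportion_draws, c(0, 0.5))
})

test_that("pairwise correlations cover the within/between-stream design", {
  series <- expand.grid(species = c("BHC", "CRC", "STJ"),
                        stream = c("indian", "todd"),
                        interval = 1:14, stringsAsFactors = FALSE)
  set.seed(11)
  base <- rnorm(14)
  series$mean <- NA_real_
  for (sp in unique(series$species)) for (st in unique(series$stream)) {
    sel <- series$species == sp & series$stream == st
    series$mean[sel] <- base + rnorm(14, 0, 0.5)
  }
  tab <- pairwise_correlations(series)
  expect_equal(sum(tab$class == "within_stream"), 6)
  expect_equal(sum(tab$class == "between_stream"), 3)
  expect_true(all(tab$r >= -1 & tab$r <= 1))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))

  # identical and mirrored series
  s2 <- series[series$stream == "indian" &
                 series$species %in% c("BHC", "CRC"), ]
  s2$mean[s2$species == "CRC"] <- s2$mean[s2$species == "BHC"]
  expect_equal(pairwise_correlations(s2)$r, 1)
  s2$mean[s2$species == "CRC"] <- -s2$mean[s2$species == "BHC"]
  expect_equal(pairwise_correlations(s2)$r, -1)

  # constant series flagged, not an error
  s3 <- s2
  s3$mean[s3$species == "CRC"] <- 0.5
  expect_true(pairwise_correlations(s3)$degenerate)
})

test_that("t-based p-values agree with a permutation oracle", {
  set.seed(21)
  for (rho in c(0, 0.5, 0.8)) {
    a <- rnorm(14)
    b <- rho * a + sqrt(1 - rho^2) * rnorm(14)
    series <- rbind(
      data.frame(species = "A", stream = "X", interval = 1:14, mean = a),
      data.frame(species = "B", stream = "X", interval = 1:14, mean = b))
    p_t <- pairwise_correlations(series)$p_value
    p_perm <- oracle_permutation_p(a, b)
    expect_lt(abs(p_t - p_perm), 0.02)
  }
})

test_that("report bundle renders and round-trips machine-readable parts", {
  icc <- data.frame(species = "A", stream = "X", icc_mean = 0.7,
                    icc_lower = 0.3, icc_upper = 0.95, icc_plugin = 0.72)
  contr <- synchrony_proportion(rexp(200), rexp(200))
  dic <- data.frame(model = c("intercept_only", "random_effects"),
                    mean_deviance = c(400, 300), pD = c(2, 20),
                    DIC = c(402, 320))
  dir <- tempfile()
  rep1 <- build_synchrony_report(icc = icc, contribution = contr,
                                 correlations = NULL, dic_table = dic,
                                 dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("icc.csv", "contribution.json", "dic.csv", "report.md")))))
  back <- jsonlite::read_json(file.path(dir, "contribution.json"),
                              simplifyVector = TRUE)
  expect_equal(back$proportion$mean, contr$proportion$mean)
  expect_equal(read.csv(file.path(dir, "icc.csv"))$icc_mean, 0.7)
  # report renders with ICC only
  txt <- readLines(file.path(dir, "report.md"))
  expect_true(any(grepl("Intra-class", txt)))
})
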