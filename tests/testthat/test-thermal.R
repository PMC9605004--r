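# Welch tests, two-stage step-up FDR, axis selection and classification.

test_that("welch_t matches closed-form arithmetic and conventions", {
  r <- welch_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_stat, -3.674235, tolerance = 1e-6)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.0213, tolerance = 1e-3)

  same <- welch_t(c(10, 20), c(10, 20))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  const <- welch_t(c(10, 10, 10), c(10, 10, 10))
  expect_true(const$degenerate)
  expect_equal(const$p_value, 1)

  apart <- welch_t(c(10, 10), c(20, 20))
  expect_true(apart$degenerate)
  expect_equal(apart$p_value, 0)

  expect_error(welch_t(1, c(2, 3)), "n >= 2")
})

test_that("bky_two_stage executes the two-stage step-up rule", {
  expect_equal(bky_two_stage(rep(1, 10), 0.01), rep(FALSE, 10))
  expect_equal(bky_two_stage(1e-12, 0.01), TRUE)
  expect_equal(bky_two_stage(c(1e-4, 2e-4, 0.5, 0.8, 0.9), 0.01),
               c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(bky_two_stage(numeric(0)), logical(0))
  expect_error(bky_two_stage(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("two-stage step-up is monotone and at least as powerful as BH", {
  withr::local_seed(13)
  for (i in 1:50) {
    p <- runif(sample(5:60, 1))^sample(1:3, 1)
    q <- 0.05
    flags <- bky_two_stage(p, q)
    bh <- p.adjust(p, "BH") <= q / (1 + q)
    expect_true(all(flags[bh]))            # superset of stage-1 BH
    if (any(flags))                        # step-up: no accepted p below
      expect_true(max(p[flags]) <= min(c(p[!flags], Inf)))  # a rejected one
  }
})

test_that("compare_groups tests every residue-pair and applies joint FDR", {
  withr::local_seed(2)
  base <- matrix(rnorm(10 * 20, 5, 0.5), 10, 20,
                 dimnames = list(NULL, aa_alphabet()))
  same <- list(a = base, b = base + rnorm(200, 0, 0.5),
               c = base + rnorm(200, 0, 0.5))
  res <- compare_groups(same, q = 0.01)
  expect_equal(nrow(res), 60)
  expect_false(any(res$rejected))

  shifted <- same
  shifted$a[, "G"] <- shifted$a[, "G"] + 8
  res2 <- compare_groups(shifted, q = 0.01)
  gly <- res2$residue == "G" & (res2$group1 == "a" | res2$group2 == "a")
  expect_true(all(res2$rejected[gly]))
  expect_false(any(res2$rejected[res2$residue == "A"]))

  expect_error(compare_groups(list(base)), "named")
  expect_error(compare_groups(list(a = base, b = base[1, , drop = FALSE])),
               "fewer than 2")
})

test_that("select_axes orders rejected residues by smallest p and caps", {
  res <- data.frame(residue = c("G", "G", "E", "Y", "A", "W"),
                    p_value = c(1e-8, 1e-6, 1e-5, 1e-4, 0.5, 1e-3),
                    rejected = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  expect_equal(select_axes(res), c("G", "E", "Y"))       # cap 3, p order
  expect_equal(select_axes(res, cap = Inf), c("G", "E", "Y", "W"))
  expect_equal(select_axes(res[1:2, ]), "G")
  res$rejected <- FALSE
  expect_error(select_axes(res), "larger panels")
})

test_that("centroids equal group means and duplication leaves them fixed", {
  panels <- generate_thermal_panels(n_per_group = 12, seed = 7)
  comps <- lapply(panels, composition_matrix)
  model <- fit_thermal_model(comps, q = 0.01)
  expect_true(all(model$axes %in% aa_alphabet()))
  for (g in names(comps))
    expect_equal(model$centroids[g, ],
                 colMeans(comps[[g]][, model$axes, drop = FALSE]))
  expect_gt(model$centroids["cold", "G"], model$centroids["mesophilic", "G"])

  dup <- lapply(comps, function(m) rbind(m, m))
  model2 <- fit_thermal_model(dup, axes = model$axes)
  expect_equal(model2$centroids, model$centroids)

  # one protein per group with pre-chosen axes: centroid = that protein
  single <- lapply(comps, function(m) m[1, , drop = FALSE])
  m1 <- fit_thermal_model(single, axes = c("G", "E", "Y"))
  expect_equal(m1$centroids["cold", ],
               single$cold[1, c("G", "E", "Y")])
})

test_that("classification is nearest-centroid with ties and axis locality", {
  panels <- generate_thermal_panels(n_per_group = 10, seed = 3)
  model <- fit_thermal_model(lapply(panels, composition_matrix),
                             axes = c("G", "E", "Y"))
  at_cold <- setNames(model$centroids["cold", ], model$axes)
  r <- classify_thermal(at_cold, model)
  expect_equal(r$label, "cold")
  expect_equal(unname(r$distances["cold"]), 0)

  # residues off the axes are ignored
  q2 <- c(at_cold, W = 99)
  expect_equal(classify_thermal(q2, model)$distances, r$distances)

  # equidistant query reports all tied labels
  mid_model <- model
  mid_model$centroids <- rbind(cold = c(10, 5, 2), thermophilic = c(14, 5, 2))
  colnames(mid_model$centroids) <- model$axes
  tie <- classify_thermal(setNames(c(12, 5, 2), model$axes), mid_model)
  expect_setequal(tie$label, c("cold", "thermophilic"))
})

test_that("cold-biased queries overwhelmingly classify as cold", {
  panels <- generate_thermal_panels(n_per_group = 20, seed = 11)
  model <- fit_thermal_model(lapply(panels, composition_matrix), q = 0.01)
  extra <- generate_thermal_panels(n_per_group = 50, seed = 1100)
  qc <- composition_matrix(extra$cold)
  labels <- vapply(seq_len(nrow(qc)), function(i)
    classify_thermal(qc[i, ], model)$label[1], character(1))
  expect_gte(mean(labels == "cold"), 0.9)
})

test_that("scatter_table rows mirror composition coordinates", {
  panels <- generate_thermal_panels(n_per_group = 5, seed = 9)
  comps <- lapply(panels, composition_matrix)
  model <- fit_thermal_model(comps, axes = c("G", "E", "Y"))
  f <- withr::local_tempfile(fileext = ".tsv")
  tab <- scatter_table(model, queries = comps$cold[1:2, ], path = f)
  expect_equal(nrow(tab), 15 + 2)
  expect_equal(names(tab), c("id", "group", "G", "E", "Y"))
  i <- which(tab$id == "cold_01" & tab$group == "cold")
  expect_equal(unlist(tab[i, c("G", "E", "Y")]),
               comps$cold["cold_01", c("G", "E", "Y")])
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back$G, tab$G)
  expect_equal(back$group, tab$group)
})
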