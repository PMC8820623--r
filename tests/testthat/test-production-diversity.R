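test_that("PDI counts distinct products regardless of value", {
  expect_equal(pdi(make_production(c("wheat", "milk", "olive_oil")))$pdi, 3)
  expect_equal(pdi(make_production(product_catalogue()$product_id))$pdi, 29)
  dup <- dplyr::bind_rows(make_production("wheat", values = 100),
                          make_production("wheat", values = 1))
  expect_equal(pdi(dup)$pdi, 1)
  token <- make_production(c("wheat", "milk"), values = c(10000, 1))
  expect_equal(pdi(token)$pdi, 2)
})

test_that("SDI follows the Simpson closed form on value shares", {
  expect_equal(sdi(make_production("wheat", values = 50))$sdi, 0)
  expect_equal(sdi(make_production(c("wheat", "milk"), values = c(5, 5)))$sdi,
               0.5)
  s <- sdi(make_production(c("wheat", "milk", "egg"),
                           values = c(0.5, 0.3, 0.2)))
  expect_equal(s$sdi, 1 - (0.25 + 0.09 + 0.04))  # 0.62
  expect_error(sdi(make_production("wheat", values = 0)), "zero total")
})

test_that("GPDI counts scorable groups only", {
  expect_equal(gpdi(make_production(c("olive_oil", "garlic")))$gpdi, 0)
  expect_equal(gpdi(make_production(c("wheat", "barley", "oat")))$gpdi, 1)
  one_per_group <- c("wheat", "bean", "almond", "milk", "beef_meat", "egg",
                     "chard", "carrot", "tomato", "grape")
  expect_equal(gpdi(make_production(one_per_group))$gpdi, 10)
  expect_equal(gpdi(make_production(c(one_per_group, "olive_oil")))$gpdi, 10)
})

test_that("GSDI aggregates to group shares and excludes unclassified value", {
  expect_equal(gsdi(make_production(c("wheat", "barley"),
                                    values = c(60, 40)))$gsdi, 0)
  g <- gsdi(make_production(c("wheat", "barley", "milk"),
                            values = c(60, 40, 100)))
  expect_equal(g$gsdi, 0.5)  # grains 100 vs dairy 100
  # olive oil value must not dilute the scorable shares
  g2 <- gsdi(make_production(c("wheat", "milk", "olive_oil"),
                             values = c(50, 50, 900)))
  expect_equal(g2$gsdi, 0.5)
  expect_error(gsdi(make_production(c("olive_oil", "garlic"))),
               class = "agridiet_no_scorable_production")
})

test_that("Simpson-type indices are invariant to currency rescaling", {
  set.seed(5)
  prods <- sample(product_catalogue()$product_id, 8)
  vals <- runif(8, 10, 1000)
  p1 <- make_production(prods, values = vals)
  p2 <- make_production(prods, values = vals * 3.72)
  expect_equal(sdi(p1)$sdi, sdi(p2)$sdi)
  expect_equal(gsdi(p1)$gsdi, gsdi(p2)$gsdi)
})

test_that("GPDI never exceeds PDI", {
  set.seed(6)
  for (i in 1:30) {
    prods <- sample(product_catalogue()$product_id, sample(1:29, 1))
    p <- make_production(prods)
    expect_lte(gpdi(p)$gpdi, pdi(p)$pdi)
  }
})

test_that("nutrient standardization matches hand-computed z-scores", {
  raw <- matrix(c(1, 2, 6,
                  10, 20, 30), ncol = 2,
                dimnames = list(c("a", "b", "c"), c("n1", "n2")))
  rni <- c(n1 = 2, n2 = 10)
  std <- standardize_nutrients(raw, rni)
  hand1 <- scale(c(0.5, 1, 3))[, 1]
  hand2 <- scale(c(1, 2, 3))[, 1]
  expect_equal(unname(std[, 1]), hand1, tolerance = 1e-12)
  expect_equal(unname(std[, 2]), hand2, tolerance = 1e-12)

  # doubling a nutrient column and its recommendation changes nothing
  raw2 <- raw; raw2[, 1] <- raw2[, 1] * 2
  rni2 <- rni; rni2["n1"] <- rni2["n1"] * 2
  expect_equal(standardize_nutrients(raw2, rni2), std)

  raw3 <- raw; raw3[, 2] <- 5
  expect_error(standardize_nutrients(raw3, rni), "n2.*zero variance")
})

test_that("distance matrix is Euclidean, symmetric, zero-diagonal", {
  m <- rbind(a = c(0, 0), b = c(3, 4), c = c(0, 0))
  d <- nutrient_distances(m)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  set.seed(9)
  x <- matrix(rnorm(5 * 7), 5, 7, dimnames = list(letters[1:5], NULL))
  dd <- nutrient_distances(x)
  for (i in 1:5) for (j in 1:5) {
    expect_equal(dd[i, j], sqrt(sum((x[i, ] - x[j, ])^2)), tolerance = 1e-12)
  }
})

test_that("dendrogram heights give path lengths equal to merge distances", {
  d <- matrix(c(0, 7, 7, 0), 2, 2, dimnames = list(c("wheat", "milk"),
                                                   c("wheat", "milk")))
  dendro <- build_dendrogram(d)
  expect_equal(nrow(dendro$edges), 2)
  expect_equal(dendro$total_branch_length, 7)  # two branches of 3.5

  # three equidistant leaves: total length independent of the tie pairing
  d3 <- matrix(2, 3, 3); diag(d3) <- 0
  dimnames(d3) <- list(c("wheat", "milk", "egg"), c("wheat", "milk", "egg"))
  dendro3 <- build_dendrogram(d3)
  expect_equal(dendro3$total_branch_length, 3)
  # ultrametric: heights non-decreasing root-ward
  expect_true(all(dendro3$edges$length >= 0))

  asym <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(build_dendrogram(asym), "symmetric")
})

test_that("NFD equals the brute-force subtree oracle on all 63 subsets", {
  dendro <- toy_dendrogram()
  leaves <- dendro$labels
  for (convention in c(TRUE, FALSE)) {
    for (mask in 1:63) {
      sel <- leaves[as.logical(bitwAnd(mask, 2^(0:5)))]
      got <- nfd(make_production(sel), dendro,
                 include_root_path = convention)$nfd
      want <- oracle_nfd(dendro, sel, include_root_path = convention)
      expect_equal(got, want, tolerance = 1e-10,
                   info = paste("mask", mask, "root", convention))
    }
  }
})

test_that("NFD is monotone under product addition and value-free", {
  dendro <- toy_dendrogram()
  leaves <- dendro$labels
  set.seed(31)
  for (i in 1:20) {
    sub <- sample(leaves, sample(1:5, 1))
    sup <- unique(c(sub, sample(leaves, 1)))
    expect_gte(nfd(make_production(sup), dendro)$nfd,
               nfd(make_production(sub), dendro)$nfd)
  }
  # monetary values are irrelevant
  expect_equal(nfd(make_production(leaves[1:3], values = c(1, 1, 1)), dendro),
               nfd(make_production(leaves[1:3], values = c(9, 0.1, 500)),
                   dendro))
  # single product still reaches the root under the default convention
  expect_gt(nfd(make_production(leaves[1]), dendro)$nfd, 0)
  expect_equal(nfd(make_production(leaves[1]), dendro,
                   include_root_path = FALSE)$nfd, 0)
  expect_error(nfd(tibble::tibble(farm_id = "f1", product_id = "potato"),
                   dendro), "not in dendrogram")
})

test_that("the full 29-product farm spans the reference dendrogram", {
  dendro <- reference_dendrogram()
  all29 <- make_production(product_catalogue()$product_id)
  expect_equal(nfd(all29, dendro)$nfd, 100)
  expect_gt(dendro$total_branch_length, 0)
  # newick export covers every product
  nwk <- as_newick(dendro)
  expect_true(all(vapply(product_catalogue()$product_id,
                         function(p) grepl(p, nwk, fixed = TRUE),
                         logical(1))))
})

test_that("self-consumption shares and orientation follow the 80% rule", {
  all_self <- make_production(c("wheat", "milk"), values = c(10, 20), self = 1)
  sh <- self_consumption_share(all_self)
  expect_equal(sh$self_share, 1)
  expect_equal(classify_orientation(all_self)$orientation,
               factor("SELF_CONSUMPTION",
                      levels = c("SELF_CONSUMPTION", "MARKET_ORIENTED",
                                 "MIXED")))
  sold <- make_production(c("wheat", "milk"), values = c(50, 50), self = 0.1)
  expect_equal(as.character(classify_orientation(sold)$orientation),
               "MARKET_ORIENTED")
  mixed <- make_production(c("wheat", "milk"), values = c(50, 50), self = 0.5)
  expect_equal(as.character(classify_orientation(mixed)$orientation), "MIXED")
  bad <- all_self; bad$frac_sold <- 0.5
  expect_error(self_consumption_share(bad), "sum to 1")
})

test_that("production_indices binds all five scores per farm", {
  set.seed(41)
  prod <- dplyr::bind_rows(
    make_production(c("wheat", "milk", "olive_oil"), values = c(1, 2, 3),
                    farm = "f1"),
    make_production(c("olive_oil", "garlic"), values = c(5, 1), farm = "f2"))
  out <- production_indices(prod)
  expect_equal(nrow(out), 2)
  expect_equal(out$pdi, c(3, 2))
  expect_true(is.na(out$gsdi[out$farm_id == "f2"]))
  expect_true(all(c("pdi", "sdi", "gpdi", "gsdi", "nfd", "self_share",
                    "orientation") %in% names(out)))
})
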