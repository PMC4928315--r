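.category_table <- function() {
  data.frame(
    species = paste0("sp", 1:8),
    diet_category = c("herbivore", "insectivore", "omnivore", "carnivore",
                      "insectivore", "herbivore", "carnivore", "omnivore"),
    foraging_behaviour = c("chew", "chew", "chew", "swallow_whole",
                           "chew", "chew", "swallow_whole", "chew"),
    pangolin_like = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    tylopod = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

test_that("diet and foraging coding schemes follow the stated conventions", {
  tb <- .category_table()

  main <- codeTraits(tb, "main_diet")
  expect_identical(unname(main$codes),
                   c(1, 1, 0.5, 0, 0, 1, 0, 0.5))  # pangolin-like -> 0
  expect_identical(main$keep, tb$species)

  iz <- codeTraits(tb, "insectivore_zero")
  expect_identical(unname(iz$codes[c("sp2", "sp5")]), c(0, 0))

  isub <- codeTraits(tb, "insectivore_subset")
  expect_false(any(c("sp1", "sp6") %in% isub$keep))
  expect_identical(unname(isub$codes[c("sp2", "sp5", "sp3", "sp4")]),
                   c(1, 0, 0.5, 0))

  hsub <- codeTraits(tb, "herbivore_subset")
  expect_false(any(c("sp2", "sp5") %in% hsub$keep))
  expect_identical(unname(hsub$codes[c("sp1", "sp3", "sp4")]), c(1, 0.5, 0))

  hnt <- codeTraits(tb, "herbivore_subset_no_tylopods")
  expect_false("sp6" %in% hnt$keep)

  fo <- codeTraits(tb, "foraging")
  expect_identical(unname(fo$codes), c(1, 1, 1, 0, 1, 1, 0, 1))

  bad <- tb; bad$diet_category[1] <- "granivore"
  expect_error(codeTraits(bad, "main_diet"), "unknown diet")
})

test_that("pruning preserves path lengths and ultrametricity", {
  tr <- simulateTimedTree(12, 80, seed = 501)
  expect_identical(pruneTimedTree(tr, tr$tip.label), tr)

  set.seed(502)
  for (r in 1:10) {
    keep <- sample(tr$tip.label, sample(3:10, 1))
    pr <- pruneTimedTree(tr, keep)
    expect_identical(sort(pr$tip.label), sort(keep))
    full <- ape::cophenetic.phylo(tr)[keep, keep]
    sub <- ape::cophenetic.phylo(pr)[keep, keep]
    expect_equal(sub, full)
    expect_silent(assertTimedTree(pr))
  }
  expect_error(pruneTimedTree(tr, tr$tip.label[1:2]), "at least 3")
  expect_error(pruneTimedTree(tr, c("spXX", tr$tip.label[1:3])), "unknown")
})

test_that("independent contrasts match the closed form and the literal recursion", {
  # 2-tip tree: single contrast (x1 - x2) / sqrt(t1 + t2)
  t2 <- ape::read.tree(text = "(a:3,b:5);")
  ct <- picContrasts(t2, c(a = 10, b = 4))
  expect_identical(nrow(ct), 1L)
  expect_equal(ct$contrast, (10 - 4) / sqrt(8))
  expect_equal(ct$var_sum, 8)

  tr <- simulateTimedTree(16, 80, seed = 503)
  x <- setNames(rnorm(16, 10, 4), tr$tip.label)

  const <- picContrasts(tr, setNames(rep(3.7, 16), tr$tip.label))
  expect_equal(max(abs(const$contrast)), 0, tolerance = 1e-12)

  mine <- picContrasts(tr, x)
  expect_identical(nrow(mine), 15L)

  # independent literal transcription of the recursion
  oracle <- picLiteral(tr, x)
  expect_lt(max(abs(mine$contrast - oracle)), 1e-12)

  # linearity: pic(a x + b) = a pic(x)
  lin <- picContrasts(tr, 2.5 * x + 7)
  expect_equal(lin$contrast, 2.5 * mine$contrast)

  # reference implementation agrees up to contrast sign
  apes <- ape::pic(x[tr$tip.label], tr)
  expect_equal(sort(abs(mine$contrast)), sort(abs(unname(apes))))

  poly <- ape::read.tree(text = "(a:1,b:1,c:1);")
  expect_error(picContrasts(poly, c(a = 1, b = 2, c = 3)), "polytom")
  resolved <- picContrasts(poly, c(a = 1, b = 2, c = 3),
                           resolve_polytomies = TRUE)
  expect_identical(nrow(resolved), 2L)
})

test_that("one-tailed Spearman matches enumeration and the t approximation", {
  expect_equal(spearmanOneTailed(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearmanOneTailed(1:10, 11 - (1:10))$rho, -1)

  set.seed(504)
  x <- rnorm(7); y <- rnorm(7)
  res <- spearmanOneTailed(x, y, "positive")
  expect_identical(res$method, "exact_permutation")
  # oracle: all 7! permutations scored independently
  perms <- bitteRep:::.permutations(7)
  rho_all <- apply(perms, 1, function(p)
    cor(x, y[p], method = "spearman"))
  expect_equal(res$p_one_tailed, mean(rho_all >= res$rho - 1e-12))

  # symmetry in the arguments; sign flip under negation
  res_yx <- spearmanOneTailed(y, x, "positive")
  expect_equal(res$p_one_tailed, res_yx$p_one_tailed)
  res_neg <- spearmanOneTailed(-x, y, "negative")
  expect_equal(res_neg$rho, -res$rho)
  expect_equal(res_neg$p_one_tailed, res$p_one_tailed)

  # large-n path agrees with the reference t approximation
  set.seed(505)
  xl <- rnorm(30); yl <- 0.4 * xl + rnorm(30)
  big <- spearmanOneTailed(xl, yl, "positive")
  expect_identical(big$method, "t_approximation")
  ref <- suppressWarnings(cor.test(xl, yl, method = "spearman",
                                   alternative = "greater", exact = FALSE))
  expect_equal(big$rho, unname(ref$estimate))
  expect_equal(big$p_one_tailed, ref$p.value, tolerance = 1e-10)

  expect_error(spearmanOneTailed(1:5, 1:4), "equal length")
  expect_identical(spearmanOneTailed(rep(1, 5), 1:5)$method, "degenerate")
})

test_that("the association test prunes, contrasts and reports the slope", {
  tr <- simulateTimedTree(41, 80, seed = 506)
  h <- evolveRepertoire(tr, 25, seed = 507)
  counts <- rowSums(tipCounts(h))
  traits <- simulateTraits(tr, counts, coupling = 2, noise_sd = 0.5,
                           seed = 508)
  tb <- data.frame(species = tr$tip.label,
                   diet_category = traits$table$diet_category,
                   foraging_behaviour = traits$table$foraging_behaviour,
                   stringsAsFactors = FALSE)
  res <- picAssociation(tr, counts, codeTraits(tb, "main_diet"))
  expect_identical(res$n_contrasts, 40L)
  expect_identical(res$n_species, 41L)
  expect_gt(res$rho, 0)
  expect_lt(res$p_one_tailed, 0.05)

  # the through-origin slope equals the no-intercept least-squares fit
  cx <- picContrasts(tr, codeTraits(tb, "main_diet")$codes)
  cy <- picContrasts(tr, counts)
  fit <- lm(cy$contrast ~ cx$contrast + 0)
  expect_equal(res$slope, unname(coef(fit)))

  # subset scheme prunes the tree and reduces the contrast count
  sub <- codeTraits(tb, "herbivore_subset")
  res2 <- picAssociation(tr, counts, sub)
  expect_identical(res2$n_species, length(sub$keep))
  expect_identical(res2$n_contrasts, length(sub$keep) - 1L)
})
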