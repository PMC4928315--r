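# Diet/foraging trait coding, Felsenstein independent contrasts and
# one-tailed Spearman association tests, including the subset analyses.

.DIET_CLASSES <- c("herbivore", "insectivore", "omnivore", "carnivore")
.FORAGING_CLASSES <- c("swallow_whole", "chew")

#' Code species diets and foraging behaviour
#'
#' Coding schemes for the expected dietary toxin exposure:
#' * `main_diet`: herbivores and insectivores 1, omnivores 0.5,
#'   carnivores 0; species flagged `pangolin_like` (hyper-specialised
#'   scent-guided insectivory) are coded 0.
#' * `insectivore_zero`: as `main_diet` but insectivores coded 0 (the
#'   earlier vertebrate-wide convention).
#' * `insectivore_subset`: herbivores dropped; insectivores 1 (flagged
#'   species 0), omnivores 0.5, carnivores 0.
#' * `herbivore_subset`: insectivores dropped; herbivores 1, omnivores 0.5,
#'   carnivores 0.
#' * `herbivore_subset_no_tylopods`: as `herbivore_subset`, additionally
#'   dropping species flagged `tylopod`.
#' * `foraging`: swallowing food whole 0, chewing 1.
#'
#' @param category_table data.frame with columns `species`, `diet_category`
#'   (herbivore/insectivore/omnivore/carnivore), `foraging_behaviour`
#'   (swallow_whole/chew) and optional logical columns `pangolin_like` and
#'   `tylopod`.
#' @param scheme one of the scheme names above.
#' @return list with `scheme`, `codes` (named vector over retained species,
#'   values in \{0, 0.5, 1\}), `keep` (species retained) and `table`.
#' @export
codeTraits <- function(category_table,
                       scheme = c("main_diet", "insectivore_zero",
                                  "insectivore_subset", "herbivore_subset",
                                  "herbivore_subset_no_tylopods",
                                  "foraging")) {
  scheme <- match.arg(scheme)
  tb <- category_table
  stopifnot(all(c("species", "diet_category", "foraging_behaviour") %in%
                  names(tb)))
  if (!all(tb$diet_category %in% .DIET_CLASSES))
    stop("unknown diet category: ",
         paste(setdiff(tb$diet_category, .DIET_CLASSES), collapse = ", "))
  if (!all(tb$foraging_behaviour %in% .FORAGING_CLASSES))
    stop("unknown foraging class: ",
         paste(setdiff(tb$foraging_behaviour, .FORAGING_CLASSES),
               collapse = ", "))
  pang <- if ("pangolin_like" %in% names(tb)) tb$pangolin_like else
    rep(FALSE, nrow(tb))
  tylo <- if ("tylopod" %in% names(tb)) tb$tylopod else rep(FALSE, nrow(tb))
  diet <- tb$diet_category
  base_code <- ifelse(diet %in% c("herbivore", "insectivore"), 1,
                      ifelse(diet == "omnivore", 0.5, 0))
  keep <- rep(TRUE, nrow(tb))
  codes <- switch(scheme,
    main_diet = ifelse(pang, 0, base_code),
    insectivore_zero = ifelse(pang | diet == "insectivore", 0, base_code),
    insectivore_subset = {
      keep <- diet != "herbivore"
      ifelse(pang, 0, base_code)
    },
    herbivore_subset = {
      keep <- diet != "insectivore"
      base_code
    },
    herbivore_subset_no_tylopods = {
      keep <- diet != "insectivore" & !tylo
      base_code
    },
    foraging = ifelse(tb$foraging_behaviour == "chew", 1, 0))
  list(scheme = scheme,
       codes = setNames(codes[keep], tb$species[keep]),
       keep = tb$species[keep], table = tb)
}

#' Prune a timed tree to a species subset
#'
#' Induced subtree on `keep`: dropped tips are removed, degree-2 nodes are
#' suppressed with their branch lengths summed, so all retained pairwise tip
#' path lengths (and ultrametricity) are preserved exactly.
#'
#' @param tree timed species tree.
#' @param keep character vector of tip labels to retain (>= 3).
#' @return the pruned `ape::phylo`.
#' @export
pruneTimedTree <- function(tree, keep) {
  if (!all(keep %in% tree$tip.label))
    stop("unknown tips: ", paste(setdiff(keep, tree$tip.label),
                                 collapse = ", "))
  if (length(keep) < 3L) stop("need at least 3 retained species")
  if (setequal(keep, tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Felsenstein phylogenetically independent contrasts
#'
#' The standard recursion: at each internal node the standardized contrast
#' is `(x_left - x_right) / sqrt(v_left + v_right)`, the node is assigned
#' the variance-weighted average of its children and its branch is
#' lengthened by `v_left * v_right / (v_left + v_right)`. Children are
#' ordered deterministically (left = the child whose smallest descendant
#' tip label sorts first), fixing contrast signs. A bifurcating tree with
#' `n` tips yields exactly `n - 1` contrasts.
#'
#' @param tree rooted bifurcating tree with positive branch lengths.
#' @param trait named numeric vector over all tips.
#' @param resolve_polytomies resolve multifurcations with near-zero
#'   (1e-8 Myr) branches instead of erroring.
#' @return data.frame with `node`, `contrast` and `var_sum` (the expected
#'   variance the contrast was standardized by), ordered by node number.
#' @export
picContrasts <- function(tree, trait, resolve_polytomies = FALSE) {
  deg <- tabulate(tree$edge[, 1L], nbins = ape::Ntip(tree) + tree$Nnode)
  if (any(deg[(ape::Ntip(tree) + 1L):length(deg)] != 2L)) {
    if (!resolve_polytomies)
      stop("tree has polytomies; set resolve_polytomies = TRUE to resolve")
    tree <- ape::multi2di(tree)
    tree$edge.length[tree$edge.length <= 0] <- 1e-8
  }
  tips <- tree$tip.label
  if (!all(tips %in% names(trait))) stop("trait missing for some tips")
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  x <- numeric(n_node)
  x[seq_len(n_tip)] <- as.numeric(trait[tips])
  extra <- numeric(n_node)
  elen <- numeric(n_node)
  elen[tree$edge[, 2L]] <- tree$edge.length
  children <- .childrenList(tree)
  # smallest descendant tip label per node, for the deterministic child order
  min_lab <- character(n_node)
  min_lab[seq_len(n_tip)] <- tips
  ord <- ape::reorder.phylo(tree, "postorder")
  internal <- unique(ord$edge[, 1L])
  for (v in internal) {
    kids <- children[[v]]
    min_lab[v] <- min(min_lab[kids])
  }
  contrast <- rep(NA_real_, n_node)
  var_sum <- rep(NA_real_, n_node)
  for (v in internal) {
    kids <- children[[v]][order(min_lab[children[[v]]])]
    c1 <- kids[1L]; c2 <- kids[2L]
    v1 <- elen[c1] + extra[c1]
    v2 <- elen[c2] + extra[c2]
    if (v1 + v2 <= 0) stop("zero expected variance at an internal node")
    contrast[v] <- (x[c1] - x[c2]) / sqrt(v1 + v2)
    var_sum[v] <- v1 + v2
    x[v] <- (x[c1] / v1 + x[c2] / v2) / (1 / v1 + 1 / v2)
    extra[v] <- v1 * v2 / (v1 + v2)
  }
  nodes <- sort(internal)
  data.frame(node = nodes, contrast = contrast[nodes],
             var_sum = var_sum[nodes])
}

# all permutations of 1..n as an (n!, n) matrix
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(p) + 1L):(i * nrow(p))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[p], nrow(p))
  }
  out
}

#' One-tailed Spearman rank correlation
#'
#' Spearman's rho on mid-ranks (average ranks for ties). The one-tailed P
#' value is computed by exact enumeration of all `n!` rank permutations
#' when `n <= exact_cutoff`, and otherwise by the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom,
#' with the tail taken in the stated direction.
#'
#' @param x,y numeric vectors of equal length (>= 3), or contrast tables
#'   from [picContrasts()].
#' @param direction `"positive"` or `"negative"` alternative.
#' @param exact_cutoff maximal n for exact permutation enumeration.
#' @return list with `rho`, `p_one_tailed`, `n` and `method`
#'   (`exact_permutation` or `t_approximation`).
#' @export
spearmanOneTailed <- function(x, y, direction = c("positive", "negative"),
                              exact_cutoff = 8L) {
  direction <- match.arg(direction)
  if (is.data.frame(x)) x <- x$contrast
  if (is.data.frame(y)) y <- y$contrast
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  sx <- stats::sd(rx); sy <- stats::sd(ry)
  if (sx == 0 || sy == 0)
    return(list(rho = NA_real_, p_one_tailed = NA_real_, n = n,
                method = "degenerate"))
  rho <- cor(rx, ry)
  if (n <= exact_cutoff) {
    perms <- .permutations(n)
    ryc <- ry - mean(ry); rxc <- rx - mean(rx)
    denom <- sqrt(sum(rxc^2)) * sqrt(sum(ryc^2))
    rho_perm <- as.numeric(matrix(ryc[perms], nrow(perms)) %*% rxc) / denom
    eps <- 1e-12
    p <- if (direction == "positive") mean(rho_perm >= rho - eps) else
      mean(rho_perm <= rho + eps)
    return(list(rho = rho, p_one_tailed = p, n = n,
                method = "exact_permutation"))
  }
  tval <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- pt(tval, df = n - 2, lower.tail = (direction == "negative"))
  p <- min(max(p, .Machine$double.xmin), 1)
  list(rho = rho, p_one_tailed = p, n = n, method = "t_approximation")
}

#' Diet/foraging association of repertoire size, via independent contrasts
#'
#' Prunes the tree to the species retained by the coding scheme, computes
#' independent contrasts of the intact-gene counts and of the codes on the
#' same tree, and tests their association with a one-tailed Spearman rank
#' correlation (default alternative: positive — more dietary toxins, more
#' receptors). The through-origin least-squares slope of count contrasts on
#' code contrasts is reported alongside (contrast regressions have no
#' intercept).
#'
#' @param tree timed species tree.
#' @param counts named vector of intact-gene counts per species.
#' @param coding result of [codeTraits()] (or a named code vector).
#' @param direction alternative direction of the test.
#' @param exact_cutoff passed to [spearmanOneTailed()].
#' @return list with `scheme`, `n_species`, `n_contrasts`, `rho`,
#'   `p_one_tailed`, `method` and `slope`.
#' @export
picAssociation <- function(tree, counts, coding,
                           direction = c("positive", "negative"),
                           exact_cutoff = 8L) {
  direction <- match.arg(direction)
  if (is.list(coding) && !is.null(coding$codes)) {
    codes <- coding$codes
    scheme <- coding$scheme
  } else {
    codes <- coding
    scheme <- "custom"
  }
  keep <- intersect(tree$tip.label, names(codes))
  keep <- intersect(keep, names(counts))
  if (length(keep) < 3L) stop("fewer than 3 species with codes and counts")
  tr <- pruneTimedTree(tree, keep)
  cx <- picContrasts(tr, codes[keep])
  cy <- picContrasts(tr, counts[keep])
  res <- spearmanOneTailed(cx$contrast, cy$contrast, direction = direction,
                           exact_cutoff = exact_cutoff)
  slope <- sum(cx$contrast * cy$contrast) / sum(cx$contrast^2)
  list(scheme = scheme, n_species = length(keep),
       n_contrasts = nrow(cx), rho = res$rho,
       p_one_tailed = res$p_one_tailed, method = res$method, slope = slope)
}
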