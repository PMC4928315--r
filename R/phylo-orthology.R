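# Distance-based gene trees and ortholog clade assignment, plus self-dotplot
# duplication detection.

# p-distance between two sequences after pairwise alignment: proportion of
# mismatching columns among columns where both sequences have an unambiguous
# base (gap and ambiguity columns are removed pairwise).
.pDistPair <- function(a, b, type = "global", gap_open = 10, gap_extend = 0.5) {
  al <- pairwiseAlignment(DNAString(a), DNAString(b), type = type,
                          substitutionMatrix =
                            Biostrings::nucleotideSubstitutionMatrix(
                              match = 1, mismatch = -1),
                          gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(alignedSubject(al)), "")[[1]]
  ok <- pa %in% c("A", "C", "G", "T") & sa %in% c("A", "C", "G", "T")
  if (!any(ok)) return(NA_real_)
  mean(pa[ok] != sa[ok])
}

#' Pairwise p-distance matrix
#'
#' Global (Needleman-Wunsch) alignment of every sequence pair, then the
#' p-distance over aligned gap-free columns; bases outside A/C/G/T are
#' treated as missing at their columns. Symmetric by construction with a
#' zero diagonal.
#'
#' @param sequences named `DNAStringSet` or character vector (>= 2).
#' @param gap_open,gap_extend affine gap penalties of the alignment.
#' @return a symmetric numeric matrix with sequence names as labels.
#' @export
pairwiseDistances <- function(sequences, gap_open = 10, gap_extend = 0.5) {
  labs <- names(sequences)
  s <- as.character(sequences)
  if (length(s) < 2L) stop("need at least 2 sequences")
  if (is.null(labs)) labs <- paste0("seq", seq_along(s))
  n <- length(s)
  D <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    D[i, j] <- D[j, i] <- .pDistPair(s[i], s[j], gap_open = gap_open,
                                     gap_extend = gap_extend)
  }
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining: iteratively join the pair minimising the
#' Q-criterion, assign branch lengths by the standard three-point formulas,
#' and reduce the matrix. Ties in Q are broken toward the lexicographically
#' lowest pair of cluster labels (a cluster is labelled by its smallest
#' member). Negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch. Exact recovery is guaranteed on additive
#' matrices.
#'
#' @param d symmetric distance matrix with labels (>= 3 taxa).
#' @return an unrooted `ape::phylo` with branch lengths.
#' @export
njTree <- function(d) {
  D <- as.matrix(d)
  labs <- rownames(D)
  if (is.null(labs)) labs <- colnames(D)
  if (is.null(labs)) stop("distance matrix must be labelled")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-8 || any(diag(D) != 0))
    stop("distance matrix must be symmetric with a zero diagonal")
  dimnames(D) <- list(labs, labs)
  newick <- setNames(labs, labs)     # newick fragment per active cluster
  key <- setNames(labs, labs)        # smallest original label per cluster

  clamp <- function(v) {
    if (v[1L] < 0) { v[2L] <- v[2L] + v[1L]; v[1L] <- 0 }
    if (v[2L] < 0) { v[1L] <- v[1L] + v[2L]; v[2L] <- 0 }
    pmax(v, 0)
  }

  while (nrow(D) > 3L) {
    m <- nrow(D)
    act <- rownames(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    pk <- apply(cand, 1L, function(ij) {
      ks <- sort(c(key[act[ij[1L]]], key[act[ij[2L]]]))
      paste(ks, collapse = "\r")
    })
    pick <- cand[order(pk)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    v <- clamp(c(vi, vj))
    a <- act[i]; b <- act[j]
    nk <- min(key[a], key[b])
    nlab <- paste0("\r", nk)  # internal cluster id, cannot collide with tips
    frag <- sprintf("(%s:%.12g,%s:%.12g)", newick[a], v[1L], newick[b], v[2L])
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    D <- D[-c(i, j), -c(i, j), drop = FALSE]
    du <- du[act[-c(i, j)]]
    D <- rbind(cbind(D, du), c(du, 0))
    rownames(D)[nrow(D)] <- colnames(D)[ncol(D)] <- nlab
    newick <- newick[setdiff(names(newick), c(a, b))]
    key <- key[setdiff(names(key), c(a, b))]
    newick[nlab] <- frag
    key[nlab] <- nk
  }
  act <- rownames(D)
  v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(v1, v2, v3), 0)  # additive input never triggers the clamp
  nwk <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);", newick[act[1L]], v[1L],
                 newick[act[2L]], v[2L], newick[act[3L]], v[3L])
  ape::read.tree(text = nwk)
}

#' Assign genes to named ortholog clades
#'
#' Every gene joins the clade of its nearest reference by p-distance
#' (free-end-gap alignment, so truncated genes are not penalised for their
#' missing ends); a gene is `unassigned` when its nearest distance exceeds
#' `distance_ceiling` or the margin between the best and the second-best
#' clade falls below `margin_rule`. The neighbour-joining tree of genes and
#' references is also returned, with a per-clade monophyly report.
#'
#' @param genes named `DNAStringSet`/character of gene sequences.
#' @param references clade-labelled `DNAStringSet`/character of reference
#'   sequences (names are clade labels; several references may share one).
#' @param margin_rule minimal best-to-second-best distance margin.
#' @param distance_ceiling maximal nearest-reference distance assigned.
#' @param tree build and return the joint NJ tree (set `FALSE` to skip).
#' @return list with `assignments` (gene_id, clade, distance, margin),
#'   `tree` (or `NULL`), and `monophyly` (clade, monophyletic).
#' @export
assignClades <- function(genes, references, margin_rule = 0.02,
                         distance_ceiling = 0.4, tree = TRUE) {
  if (length(references) == 0L) stop("reference set must be non-empty")
  gnames <- names(genes); clades <- names(references)
  g <- as.character(genes); rf <- as.character(references)
  names(g) <- if (is.null(gnames)) paste0("gene", seq_along(g)) else gnames
  rows <- lapply(seq_along(g), function(i) {
    d <- vapply(rf, function(r) .pDistPair(g[i], r, type = "overlap"),
                numeric(1))
    best_per_clade <- tapply(d, clades, min)
    o <- order(best_per_clade)
    best <- best_per_clade[o[1L]]
    second <- if (length(o) > 1L) best_per_clade[o[2L]] else Inf
    margin <- second - best
    lab <- if (is.na(best) || best > distance_ceiling || margin < margin_rule)
      "unassigned" else names(best_per_clade)[o[1L]]
    data.frame(gene_id = names(g)[i], clade = lab, distance = unname(best),
               margin = unname(margin), stringsAsFactors = FALSE)
  })
  assignments <- do.call(rbind, rows)
  joint_tree <- NULL
  mono <- data.frame(clade = character(), monophyletic = logical(),
                     stringsAsFactors = FALSE)
  if (tree && length(g) + length(rf) >= 3L) {
    ref_labs <- sprintf("ref|%s|%d", clades, seq_along(rf))
    all_seqs <- c(setNames(g, names(g)), setNames(rf, ref_labs))
    D <- pairwiseDistances(all_seqs)
    joint_tree <- njTree(D)
    mono <- do.call(rbind, lapply(unique(clades), function(cl) {
      tips <- c(ref_labs[clades == cl],
                assignments$gene_id[assignments$clade == cl])
      ok <- if (length(tips) < 2L) TRUE else
        ape::is.monophyletic(joint_tree, tips)
      data.frame(clade = cl, monophyletic = ok, stringsAsFactors = FALSE)
    }))
  }
  list(assignments = assignments, tree = joint_tree, monophyly = mono)
}

#' Self-comparison dotplot
#'
#' All exact word matches of a sequence against itself, on both strands,
#' reported as coordinate pairs; off-diagonal collinear runs spanning at
#' least `min_block` bp are chained into duplicated blocks.
#'
#' @param sequence a `DNAString` or character sequence.
#' @param word_size exact word length, bp (>= 8).
#' @param min_block minimal chained block span reported, bp.
#' @return list with `matches` (x, y, strand; 1-based word starts) and
#'   `blocks` (x_start, x_end, y_start, y_end, span, strand; 1-based
#'   inclusive).
#' @export
selfDotplot <- function(sequence, word_size = 15L, min_block = 100L) {
  if (word_size < 8L) stop("word_size must be >= 8")
  s <- as.character(sequence)
  L <- nchar(s)
  w <- as.integer(word_size)
  fw <- .words(s, w)
  rows <- list()
  tab <- split(seq_along(fw), fw)
  for (pos in tab) {
    if (length(pos) >= 1L) {
      pr <- expand.grid(x = pos, y = pos)
      rows[[length(rows) + 1L]] <- data.frame(pr, strand = "+",
                                              stringsAsFactors = FALSE)
    }
  }
  rcw <- .words(revcomp(s), w)
  rtab <- split(seq_along(rcw), rcw)
  shared <- intersect(names(tab), names(rtab))
  for (word in shared) {
    x <- tab[[word]]
    y <- L - rtab[[word]] - w + 2L  # forward start of the rc word
    pr <- expand.grid(x = x, y = y)
    rows[[length(rows) + 1L]] <- data.frame(pr, strand = "-",
                                            stringsAsFactors = FALSE)
  }
  matches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(x = integer(), y = integer(), strand = character())
  matches <- matches[order(matches$strand, matches$x, matches$y), ]
  rownames(matches) <- NULL

  chain <- function(xs, ys, anti) {
    # collinear run: x increases by 1 while y increases (or decreases) by 1
    o <- order(xs)
    xs <- xs[o]; ys <- ys[o]
    brk <- cumsum(c(TRUE, diff(xs) != 1L))
    out <- list()
    for (ids in split(seq_along(xs), brk)) {
      span <- length(ids) + w - 1L
      if (span >= min_block)
        out[[length(out) + 1L]] <- data.frame(
          x_start = xs[ids[1L]], x_end = xs[ids[length(ids)]] + w - 1L,
          y_start = min(ys[ids]), y_end = max(ys[ids]) + w - 1L,
          span = span, strand = if (anti) "-" else "+",
          stringsAsFactors = FALSE)
    }
    out
  }
  blocks <- list()
  plus <- matches[matches$strand == "+" & matches$x != matches$y, ]
  if (nrow(plus)) {
    for (off in split(plus, plus$y - plus$x))
      blocks <- c(blocks, chain(off$x, off$y, anti = FALSE))
  }
  minus <- matches[matches$strand == "-", ]
  if (nrow(minus)) {
    for (off in split(minus, minus$x + minus$y))
      blocks <- c(blocks, chain(off$x, off$y, anti = TRUE))
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(x_start = integer(), x_end = integer(), y_start = integer(),
               y_end = integer(), span = integer(), strand = character())
  list(matches = matches, blocks = blocks)
}
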