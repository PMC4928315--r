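# Ancestral repertoire reconstruction: Dollo single-origin presence and
# per-clade linear-cost (Sankoff) parsimony for copy numbers, yielding
# per-branch gain (duplication) and loss (pseudogenisation/deletion) counts.

.childrenList <- function(tree) {
  n_node <- ape::Ntip(tree) + tree$Nnode
  ch <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge)))
    ch[[tree$edge[i, 1L]]] <- c(ch[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  ch
}

# carrier[v]: does any descendant tip of v (v included) carry the clade?
.carrierSweep <- function(post_edge, n_node, tip_carries) {
  carrier <- logical(n_node)
  carrier[seq_along(tip_carries)] <- tip_carries
  for (i in seq_len(nrow(post_edge)))
    carrier[post_edge[i, 1L]] <- carrier[post_edge[i, 1L]] ||
      carrier[post_edge[i, 2L]]
  carrier
}

# MRCA of the carrier tips: descend from the root while exactly one child
# subtree carries the clade
.mrcaFromCarrier <- function(children, n_tip, carrier) {
  v <- n_tip + 1L
  repeat {
    if (v <= n_tip) return(v)
    on <- children[[v]][carrier[children[[v]]]]
    if (length(on) == 1L) v <- on else return(v)
  }
}

.subtreeFrom <- function(children, node) {
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    out <- c(out, v)
    stack <- c(stack, children[[v]])
  }
  out
}

#' Dollo reconstruction of clade presence
#'
#' A clade originates exactly once, at the most recent common ancestor of
#' the tips carrying it; states above that node are absent, and below it
#' losses are placed to minimise the loss count (a branch is a loss branch
#' when its parent is present and no tip below the branch carries the
#' clade).
#'
#' @param tree rooted species tree (`ape::phylo`).
#' @param presence named 0/1 (or logical) vector over all tips.
#' @return list with `states` (0/1 per node, tips first), `origin` (node
#'   where the clade arises, `NA` if absent everywhere), `loss_edges`
#'   (data.frame parent, child) and `n_losses`.
#' @export
dolloPresence <- function(tree, presence) {
  tips <- tree$tip.label
  if (!all(tips %in% names(presence)))
    stop("presence must be defined for all tips")
  pres <- as.integer(presence[tips] > 0)
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  states <- integer(n_node)
  if (sum(pres) == 0L)
    return(list(states = states, origin = NA_integer_,
                loss_edges = data.frame(parent = integer(), child = integer()),
                n_losses = 0L))
  children <- .childrenList(tree)
  post_edge <- ape::reorder.phylo(tree, "postorder")$edge
  carrier <- .carrierSweep(post_edge, n_node, pres > 0L)
  mrca <- .mrcaFromCarrier(children, n_tip, carrier)
  sub <- .subtreeFrom(children, mrca)
  states[sub] <- as.integer(carrier[sub])
  loss <- tree$edge[states[tree$edge[, 1L]] == 1L &
                      states[tree$edge[, 2L]] == 0L, , drop = FALSE]
  list(states = states, origin = mrca,
       loss_edges = data.frame(parent = loss[, 1L], child = loss[, 2L]),
       n_losses = nrow(loss))
}

# Constrained Sankoff for one clade: states 0..M, zero above the MRCA of
# carrier tips, state >= 1 at the MRCA, and no regain (a parent at 0 forces
# its children to 0). Returns the per-node state vector. `post_edge` is the
# tree's edge matrix in postorder.
.sankoffClade <- function(tree, counts, children, post_edge) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  states <- integer(n_node)
  cnt <- as.integer(counts[tips])
  if (all(cnt == 0L)) return(states)
  M <- max(cnt)
  carrier <- .carrierSweep(post_edge, n_node, cnt > 0L)
  mrca <- .mrcaFromCarrier(children, n_tip, carrier)
  sub <- .subtreeFrom(children, mrca)
  in_sub <- logical(n_node); in_sub[sub] <- TRUE
  S <- 0:M
  INF <- .Machine$integer.max / 4
  cost <- matrix(INF, n_node, M + 1L)
  for (t in seq_len(n_tip)) {
    cost[t, ] <- INF
    cost[t, cnt[t] + 1L] <- 0
  }
  internal <- unique(post_edge[, 1L])  # postorder: children before parents
  for (v in internal) {
    if (!in_sub[v]) next
    acc <- numeric(M + 1L)
    for (chn in children[[v]]) {
      ch_cost <- cost[chn, ]
      trans <- vapply(S, function(s) {
        if (s == 0L) ch_cost[1L] else min(ch_cost + abs(s - S))
      }, numeric(1))
      acc <- acc + trans
    }
    cost[v, ] <- acc
  }
  allowed <- 2L:(M + 1L)  # state >= 1 at the origin node
  root_costs <- if (mrca <= n_tip) {
    ifelse(S == cnt[mrca], 0, INF)[allowed]
  } else cost[mrca, allowed]
  s_mrca <- S[allowed][which(root_costs == min(root_costs))[1L]]
  states[mrca] <- s_mrca
  # preorder within the subtree
  for (i in rev(seq_len(nrow(post_edge)))) {
    p <- post_edge[i, 1L]; chn <- post_edge[i, 2L]
    if (!in_sub[p] || !in_sub[chn]) next
    sp <- states[p]
    if (chn <= n_tip) { states[chn] <- cnt[chn]; next }
    if (sp == 0L) { states[chn] <- 0L; next }
    tot <- cost[chn, ] + abs(sp - S)
    states[chn] <- S[which(tot == min(tot))[1L]]
  }
  states
}

#' Ancestral copy counts and per-branch gains/losses
#'
#' Per clade, ancestral intact copy numbers are reconstructed by linear-cost
#' (Sankoff) parsimony over integer states 0..max observed, under a Dollo
#' single-origin constraint: the clade is absent above the most recent
#' common ancestor of the tips carrying it, present there, and never
#' regained once lost. Among co-optimal origin states the minimum is
#' reported. Per branch, gains are `sum_clades max(0, child - parent)` and
#' losses `sum_clades max(0, parent - child)`; copies appearing at a
#' clade's origin node are booked as gains on the branch entering it.
#'
#' @param tree rooted bifurcating species tree.
#' @param counts species x clade matrix of intact copy counts (row names are
#'   species; must cover all tips).
#' @return list with `edges` (parent, child, child_label, gains, losses),
#'   `node_counts` (nodes x clades), `node_intact` (total per node) and
#'   `tree`.
#' @export
ancestralCounts <- function(tree, counts) {
  tips <- tree$tip.label
  if (!all(tips %in% rownames(counts)))
    stop("counts missing species: ",
         paste(setdiff(tips, rownames(counts)), collapse = ", "))
  counts <- counts[tips, , drop = FALSE]
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  children <- .childrenList(tree)
  post_edge <- ape::reorder.phylo(tree, "postorder")$edge
  clades <- colnames(counts)
  if (is.null(clades)) clades <- paste0("clade", seq_len(ncol(counts)))
  node_counts <- matrix(0L, n_node, ncol(counts),
                        dimnames = list(NULL, clades))
  for (j in seq_len(ncol(counts)))
    node_counts[, j] <- .sankoffClade(tree, counts[, j], children, post_edge)
  ep <- tree$edge[, 1L]; ec <- tree$edge[, 2L]
  dif <- node_counts[ec, , drop = FALSE] - node_counts[ep, , drop = FALSE]
  gains <- rowSums(pmax(dif, 0L))
  losses <- rowSums(pmax(-dif, 0L))
  child_label <- ifelse(ec <= n_tip, tips[ec], as.character(ec))
  edges <- data.frame(parent = ep, child = ec, child_label = child_label,
                      gains = as.integer(gains), losses = as.integer(losses),
                      stringsAsFactors = FALSE)
  list(edges = edges, node_counts = node_counts,
       node_intact = rowSums(node_counts), tree = tree)
}

#' Lower bound on the root repertoire
#'
#' The number of clades inferred present (count >= 1) at the root of the
#' species tree — under Dollo logic, a conservative lower bound on the
#' ancestral intact repertoire (a clade surviving on both sides of the root
#' must have been present in the common ancestor).
#'
#' @param summary result of [ancestralCounts()].
#' @return integer clade count.
#' @export
rootRepertoireBound <- function(summary) {
  root <- ape::Ntip(summary$tree) + 1L
  sum(summary$node_counts[root, ] >= 1L)
}

#' Write the per-branch event table and the annotated tree
#'
#' The event table is a TSV (parent, child, child_label, gains, losses); the
#' tree is written as Newick with inferred intact counts as internal node
#' labels, mirroring the usual repertoire-evolution display.
#'
#' @param summary result of [ancestralCounts()].
#' @param dir output directory.
#' @return invisibly, the files written.
#' @export
writeBranchEvents <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fe <- file.path(dir, "branch_events.tsv")
  write.table(summary$edges, fe, sep = "\t", quote = FALSE, row.names = FALSE)
  tr <- summary$tree
  n_tip <- ape::Ntip(tr)
  tr$node.label <- summary$node_intact[(n_tip + 1L):length(summary$node_intact)]
  ft <- file.path(dir, "annotated_tree.nwk")
  ape::write.tree(tr, ft)
  invisible(c(fe, ft))
}
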