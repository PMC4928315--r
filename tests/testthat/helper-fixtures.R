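# Shared fixtures and independent oracles used across the test files.

.fix_env <- new.env(parent = emptyenv())

# small planted cohort (cached per test file): 4 species, 12 clades
smallCohort <- function() {
  if (!is.null(.fix_env$cohort)) return(.fix_env$cohort)
  tmpl <- cladeTemplates(12L, seed = 101L)
  tree <- simulateTimedTree(4L, 80, seed = 102L)
  hist <- evolveRepertoire(tree, root_clades = 10L, gain_rate = 0.004,
                           loss_rate = 0.006,
                           clade_labels = names(tmpl)[1:10], seed = 103L)
  planted <- plantGenomes(hist, tmpl, seed = 104L)
  .fix_env$cohort <- list(templates = tmpl, tree = tree, history = hist,
                          genomes = planted$genomes,
                          ledger = ledgerTable(planted$ledger))
  .fix_env$cohort
}

# deterministic reverse translation: first codon of each amino acid
aaToNt <- function(aa) {
  tab <- bitteRep:::.CODON_TABLE
  paste(vapply(strsplit(aa, "")[[1]], function(a) tab[[a]][1L], character(1)),
        collapse = "")
}

# seven-TM protein with a configurable hydrophilic tail; ORF length is
# 3 * (nchar(protein) + 1) once the stop codon is appended
sevenTmProtein <- function(tail_len = 30L) {
  paste0("M", strrep("N", 4),
         paste(rep(c(strrep("I", 23), strrep("D", 9)), 6), collapse = ""),
         strrep("I", 23), strrep("D", tail_len))
}

sevenTmOrf <- function(tail_len = 30L) {
  paste0(aaToNt(sevenTmProtein(tail_len)), "TAA")
}

# substitution-only mutant at a given per-site rate (no indels)
mutateSeq <- function(s, rate, seed) {
  set.seed(seed)
  v <- strsplit(s, "")[[1]]
  hit <- which(runif(length(v)) < rate)
  for (i in hit) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  paste(v, collapse = "")
}

# brute-force transitive merge of hit intervals (quadratic union-find)
bruteMerge <- function(hits) {
  out <- list()
  for (g in unique(paste(hits$contig, hits$strand))) {
    idx <- which(paste(hits$contig, hits$strand) == g)
    comp <- seq_along(idx)
    repeat {
      changed <- FALSE
      for (a in seq_along(idx)) for (b in seq_along(idx)) {
        if (comp[a] != comp[b] &&
            hits$start[idx[a]] < hits$end[idx[b]] &&
            hits$end[idx[a]] > hits$start[idx[b]]) {
          comp[comp == comp[b]] <- comp[a]; changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      sel <- idx[comp == cc]
      out[[length(out) + 1L]] <- data.frame(
        contig = hits$contig[sel[1L]], strand = hits$strand[sel[1L]],
        start = min(hits$start[sel]), end = max(hits$end[sel]),
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, out)
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

# exhaustive ORF enumeration: all ATG..stop spans (1-based inclusive, stop
# included) in a character sequence, all three frames
bruteOrfs <- function(s) {
  n <- nchar(s)
  res <- list()
  for (f in 0:2) {
    starts <- seq(1L + f, n - 2L, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    stop_i <- which(codons %in% c("TAA", "TAG", "TGA"))
    atg_i <- which(codons == "ATG")
    for (si in stop_i) {
      prev <- stop_i[stop_i < si]
      lo <- if (length(prev)) max(prev) + 1L else 1L
      a <- atg_i[atg_i >= lo & atg_i < si]
      if (length(a))
        res[[length(res) + 1L]] <- c(starts[min(a)], starts[si] + 2L)
    }
  }
  if (!length(res)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, res))
  data.frame(start = m[, 1L], end = m[, 2L])
}

# literal recursive transcription of the Felsenstein contrast algorithm,
# independent of the package's iterative implementation
picLiteral <- function(tree, x) {
  n_tip <- ape::Ntip(tree)
  kids <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  elen <- numeric(n_tip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  min_tip <- function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    min(vapply(kids[[v]], min_tip, character(1)))
  }
  contrasts <- list()
  rec <- function(v) {
    if (v <= n_tip)
      return(c(val = unname(x[tree$tip.label[v]]), var = elen[v]))
    ch <- kids[[v]][order(vapply(kids[[v]], min_tip, character(1)))]
    a <- rec(ch[1L]); b <- rec(ch[2L])
    contrasts[[as.character(v)]] <<-
      unname((a["val"] - b["val"]) / sqrt(a["var"] + b["var"]))
    val <- (a["val"] / a["var"] + b["val"] / b["var"]) /
      (1 / a["var"] + 1 / b["var"])
    c(val = unname(val),
      var = unname(elen[v] + a["var"] * b["var"] / (a["var"] + b["var"])))
  }
  rec(n_tip + 1L)
  out <- unlist(contrasts)
  out[order(as.integer(names(contrasts)))]
}

# brute-force single-origin (Dollo) parsimony on 0/1 tip states:
# enumerates every internal labeling, keeps those with exactly one origin
# (a 0->1 edge, or a presence state at the root), and returns the minimal
# loss count plus the minimal total-change cost
bruteDollo <- function(tree, pres) {
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  ep <- tree$edge[, 1L]; ec <- tree$edge[, 2L]
  combos <- as.matrix(expand.grid(rep(list(0:1), n_int)))
  states <- cbind(matrix(rep(pres, each = nrow(combos)), nrow(combos)),
                  combos)
  P <- states[, ep, drop = FALSE]; C <- states[, ec, drop = FALSE]
  gains <- rowSums(P == 0 & C == 1)
  losses <- rowSums(P == 1 & C == 0)
  origins <- gains + states[, n_tip + 1L]
  valid <- origins == 1L
  if (!any(valid)) return(list(min_losses = NA, min_cost = NA))
  list(min_losses = min(losses[valid]),
       min_cost = min((gains + losses)[valid]))
}
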