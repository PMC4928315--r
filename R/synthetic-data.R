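# Synthetic-data generator: timed species trees, clade repertoire histories,
# planted receptor genes with a ground-truth ledger, and diet codes optionally
# coupled to repertoire size.

.CODON_TABLE <- list(
  A = c("GCT", "GCC", "GCA", "GCG"), R = c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"),
  N = c("AAT", "AAC"), D = c("GAT", "GAC"), C = c("TGT", "TGC"),
  Q = c("CAA", "CAG"), E = c("GAA", "GAG"), G = c("GGT", "GGC", "GGA", "GGG"),
  H = c("CAT", "CAC"), I = c("ATT", "ATC", "ATA"),
  L = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"), K = c("AAA", "AAG"),
  M = "ATG", F = c("TTT", "TTC"), P = c("CCT", "CCC", "CCA", "CCG"),
  S = c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
  T = c("ACT", "ACC", "ACA", "ACG"), W = "TGG", Y = c("TAT", "TAC"),
  V = c("GTT", "GTC", "GTA", "GTG"))

# Shared 300-residue seven-transmembrane receptor scaffold: M + N-loop,
# 7 hydrophobic TM stretches of 23 residues separated by 6 hydrophilic
# 15-residue loops, hydrophilic C-tail. Methionine never recurs after the
# start so a lost start cannot be rescued by a downstream in-frame ATG.
.templateProtein <- function() {
  tm_pool <- c("I", "L", "V", "F")
  loop_pool <- c("D", "E", "K", "N", "R", "S", "T", "Q")
  seg <- function(n, pool) sample(pool, n, replace = TRUE)
  aa <- c("M", seg(11, loop_pool))
  for (k in 1:7) {
    aa <- c(aa, seg(23, tm_pool))
    if (k < 7) aa <- c(aa, seg(15, loop_pool))
  }
  aa <- c(aa, seg(37, loop_pool))
  paste(aa, collapse = "")
}

.reverseTranslate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    opts <- .CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Build synthetic receptor clade templates
#'
#' Generates `n_clades` nucleotide ORF templates standing in for the named
#' bitter-receptor ortholog clades. All clades share one 300-residue
#' seven-transmembrane protein scaffold; clades differ by independent
#' synonymous codon choices, giving within-clade identity 100% and
#' appreciable between-clade nucleotide divergence. Every template is a
#' 903 bp ORF (start codon, no internal stop, terminal stop) whose
#' translation yields exactly seven transmembrane segments under
#' [countTmSegments()] defaults; this is asserted at build time.
#'
#' @param n_clades number of clade templates (default 28, the number of
#'   Boreoeutherian TAS2R clades the real nomenclature recognises).
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet] of ORF templates.
#' @export
cladeTemplates <- function(n_clades = 28L, seed = 1L) {
  set.seed(seed)
  protein <- .templateProtein()
  labels <- sprintf("TAS2R%02d", seq_len(n_clades))
  seqs <- vapply(labels, function(lab) {
    paste0(.reverseTranslate(protein), sample(c("TAA", "TAG", "TGA"), 1L))
  }, character(1))
  templates <- DNAStringSet(seqs)
  names(templates) <- labels
  for (i in seq_along(templates)) checkTemplate(templates[[i]])
  templates
}

#' Validate a receptor template against the planting preconditions
#'
#' A template must be a length-multiple-of-3 ORF longer than 750 bp that
#' starts with ATG, ends with a stop codon, contains no internal in-frame
#' stop, and whose translation shows exactly seven transmembrane segments
#' under the default hydropathy caller.
#'
#' @param template a [Biostrings::DNAString] or character ORF sequence.
#' @return invisibly `TRUE`; errors with class `invalid_template` otherwise.
#' @export
checkTemplate <- function(template) {
  s <- as.character(template)
  fail <- function(msg) stop(errorCondition(msg, class = "invalid_template"))
  if (nchar(s) %% 3L != 0L) fail("template length must be a multiple of 3")
  if (nchar(s) <= 750L) fail("template must be > 750 bp")
  if (substr(s, 1L, 3L) != "ATG") fail("template must start with ATG")
  codons <- substring(s, seq(1L, nchar(s) - 2L, by = 3L),
                      seq(3L, nchar(s), by = 3L))
  stops <- codons %in% c("TAA", "TAG", "TGA")
  if (!stops[length(codons)]) fail("template must end with a stop codon")
  if (any(stops[-length(codons)])) fail("template has an internal stop codon")
  prot <- paste(vapply(codons[-length(codons)],
                       function(cd) names(which(vapply(.CODON_TABLE, function(v)
                         cd %in% v, logical(1)))), character(1)), collapse = "")
  if (countTmSegments(prot) != 7L)
    fail("template translation must show exactly 7 transmembrane segments")
  invisible(TRUE)
}

#' Simulate a time-calibrated species tree
#'
#' Pure-birth (Yule) topology with `n_tips` tips, rescaled so the crown
#' (root) age equals `crown_age` million years. The result is rooted,
#' strictly bifurcating and ultrametric.
#'
#' @param n_tips number of tips (>= 2).
#' @param crown_age root age in Myr.
#' @param seed integer seed.
#' @return an `ape::phylo` with tip labels `sp01`, `sp02`, ...
#' @export
simulateTimedTree <- function(n_tips, crown_age = 80, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  if (crown_age <= 0) stop("crown_age must be > 0")
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(nodeDepths(tree))
  tree$edge.length <- tree$edge.length * (crown_age / depth)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  assertTimedTree(tree)
  tree
}

#' Evolve a clade repertoire along a species tree
#'
#' Starting from `root_clades` single-copy intact clades at the root, draws
#' Poisson numbers of gain (duplication) and loss events on every branch,
#' proportional to branch length, independently per clade. A gain adds one
#' copy of a clade that currently has at least one copy; a loss removes one
#' copy and is either a pseudogenisation (leaving a disrupted copy in the
#' descendant genomes) or a whole-gene deletion, with equal probability.
#' Counts never drop below zero.
#'
#' @param tree a timed species tree ([simulateTimedTree()]).
#' @param root_clades number of clades intact (one copy) at the root.
#' @param gain_rate gain events per clade per Myr.
#' @param loss_rate loss events per clade per Myr.
#' @param clade_labels optional labels; defaults to `TAS2R01`, ...
#' @param seed integer seed.
#' @return a [RepertoireHistory-class] object.
#' @export
evolveRepertoire <- function(tree, root_clades = 25L, gain_rate = 0.005,
                             loss_rate = 0.007, clade_labels = NULL,
                             seed = 1L) {
  if (gain_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  if (root_clades < 0L) stop("root_clades must be >= 0")
  assertTimedTree(tree)
  set.seed(seed)
  clades <- if (is.null(clade_labels))
    sprintf("TAS2R%02d", seq_len(root_clades)) else clade_labels
  if (length(clades) != root_clades) stop("clade_labels length mismatch")
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  counts <- matrix(0L, n_node, max(root_clades, 1L),
                   dimnames = list(NULL, if (root_clades > 0L) clades else NULL))
  if (root_clades == 0L) counts <- counts[, 0, drop = FALSE]
  root <- n_tip + 1L
  if (root_clades > 0L) counts[root, ] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  ev <- list()
  # preorder over edges: reverse postorder guarantees parent counts are set
  for (i in rev(seq_len(nrow(ord$edge)))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]; len <- ord$edge.length[i]
    cc <- counts[p, ]
    for (j in seq_along(cc)) {
      gains <- if (cc[j] > 0L) rpois(1L, gain_rate * len) else 0L
      losses <- min(rpois(1L, loss_rate * len), cc[j] + gains)
      cc[j] <- cc[j] + gains - losses
      if (gains > 0L)
        ev[[length(ev) + 1L]] <- data.frame(
          parent = p, child = ch, clade = clades[j], type = "gain",
          n = gains, stringsAsFactors = FALSE)
      if (losses > 0L) {
        kinds <- sample(c("loss_pseudogene", "loss_deletion"), losses,
                        replace = TRUE)
        for (k in unique(kinds))
          ev[[length(ev) + 1L]] <- data.frame(
            parent = p, child = ch, clade = clades[j], type = k,
            n = sum(kinds == k), stringsAsFactors = FALSE)
      }
    }
    counts[ch, ] <- cc
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(parent = integer(), child = integer(), clade = character(),
               type = character(), n = integer(), stringsAsFactors = FALSE)
  new("RepertoireHistory", tree = tree, counts = counts, events = events,
      clades = clades)
}

# Count pseudogenisation losses accumulated on the root-to-tip path, per clade.
.pseudogeneLoad <- function(history, tip_index) {
  tree <- history@tree
  ev <- history@events
  load <- setNames(integer(length(history@clades)), history@clades)
  if (nrow(ev) == 0L) return(load)
  # collect edges on the path root -> tip
  parent <- integer(ape::Ntip(tree) + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  node <- tip_index
  root <- ape::Ntip(tree) + 1L
  path_children <- integer(0)
  while (node != root) {
    path_children <- c(path_children, node)
    node <- parent[node]
  }
  sel <- ev$type == "loss_pseudogene" & ev$child %in% path_children
  if (any(sel)) {
    agg <- tapply(ev$n[sel], ev$clade[sel], sum)
    load[names(agg)] <- load[names(agg)] + as.integer(agg)
  }
  load
}

.mutPrematureStop <- function(s) {
  n_cod <- nchar(s) %/% 3L
  idx <- sample(seq(max(2L, round(0.25 * n_cod)), round(0.75 * n_cod)), 1L)
  substr(s, 3L * idx - 2L, 3L * idx) <- "TAA"
  s
}

.mutFrameshift <- function(s) {
  dlen <- sample(1:2, 1L)
  pos <- sample(seq(round(0.25 * nchar(s)), round(0.75 * nchar(s))), 1L)
  paste0(substr(s, 1L, pos - 1L), substr(s, pos + dlen, nchar(s)))
}

.mutLostStart <- function(s) {
  substr(s, 1L, 3L) <- "GTG"
  s
}

#' Plant receptor genes into synthetic contigs
#'
#' Realises a [RepertoireHistory-class] as genome assemblies: each tip's
#' intact copies are planted verbatim from the clade templates, except a
#' `partial_fraction` that are truncated and placed within `edge_margin` bp
#' of a contig end (emulating assembly truncation); pseudogenisation losses
#' accumulated on the tip's root path are planted as disrupted copies
#' carrying one disruption drawn from `disrupt_spec`. Strands are random;
#' flanking sequence is i.i.d. with GC content `gc`, and an in-frame stop
#' codon is placed immediately upstream of every full-length planted ORF so
#' the open reading frame cannot extend into flank.
#'
#' @param history a [RepertoireHistory-class].
#' @param templates clade-named `DNAStringSet` passing [checkTemplate()];
#'   must cover all clades in `history`.
#' @param contig_length length of every synthetic contig, bp.
#' @param partial_fraction expected fraction of intact copies planted as
#'   contig-edge partials.
#' @param disrupt_spec named probability vector over
#'   `premature_stop`, `frameshift_indel`, `lost_start`.
#' @param edge_margin maximal flank between a partial gene and its contig
#'   end, bp (default 30, the partial-gene rule it exercises).
#' @param genes_per_contig maximal full-length genes packed per contig.
#' @param gc flanking-sequence GC content.
#' @param seed integer seed.
#' @return `list(genomes = <list of GenomeAssembly>, ledger = <TruthLedger>)`.
#' @export
plantGenomes <- function(history, templates, contig_length = 12000L,
                         partial_fraction = 0.1,
                         disrupt_spec = c(premature_stop = 1/3,
                                          frameshift_indel = 1/3,
                                          lost_start = 1/3),
                         edge_margin = 30L, genes_per_contig = 4L, gc = 0.5,
                         seed = 1L) {
  for (i in seq_along(templates)) checkTemplate(templates[[i]])
  if (contig_length <= max(width(templates)))
    stop("contig_length must exceed the longest template")
  missing_cl <- setdiff(history@clades, names(templates))
  if (length(missing_cl))
    stop("templates missing for clades: ", paste(missing_cl, collapse = ", "))
  set.seed(seed)
  tree <- history@tree
  tips <- tree$tip.label
  tip_mat <- tipCounts(history)
  genomes <- list()
  ledger_rows <- list()

  for (ti in seq_along(tips)) {
    sp <- tips[ti]
    units <- list()   # each: list(seq, clade, status, disruptions, edge)
    for (cl in history@clades) {
      tmpl <- as.character(templates[[cl]])
      n_int <- tip_mat[sp, cl]
      if (n_int > 0L) {
        is_partial <- runif(n_int) < partial_fraction
        for (k in seq_len(n_int)) {
          if (is_partial[k]) {
            frac <- runif(1, 0.4, 0.85)
            keep <- round(frac * nchar(tmpl))
            side <- sample(c("head", "tail"), 1L)
            sq <- if (side == "tail") substr(tmpl, 1L, keep) else
              substr(tmpl, nchar(tmpl) - keep + 1L, nchar(tmpl))
            units[[length(units) + 1L]] <- list(
              seq = sq, clade = cl, status = "partial", disruptions = "",
              cut = side)
          } else {
            units[[length(units) + 1L]] <- list(
              seq = tmpl, clade = cl, status = "complete", disruptions = "",
              cut = NA_character_)
          }
        }
      }
      n_dis <- .pseudogeneLoad(history, ti)[cl]
      for (k in seq_len(n_dis)) {
        kind <- if (length(disrupt_spec) == 0L) NA_character_ else
          sample(names(disrupt_spec), 1L, prob = disrupt_spec)
        sq <- switch(kind,
                     premature_stop = .mutPrematureStop(tmpl),
                     frameshift_indel = .mutFrameshift(tmpl),
                     lost_start = .mutLostStart(tmpl),
                     tmpl)
        units[[length(units) + 1L]] <- list(
          seq = sq, clade = cl, status = "disrupted",
          disruptions = if (is.na(kind)) "" else kind, cut = NA_character_)
      }
    }

    contigs <- character(0)
    k_contig <- 0L
    new_contig_name <- function() {
      k_contig <<- k_contig + 1L
      sprintf("%s|contig_%d", sp, k_contig)
    }
    add_row <- function(contig, start, end, strand, u) {
      ledger_rows[[length(ledger_rows) + 1L]] <<- data.frame(
        gene_id = .geneId(sp, contig, start, end, strand), species = sp,
        contig = contig, start = start, end = end, strand = strand,
        clade = u$clade, true_status = u$status, disruptions = u$disruptions,
        stringsAsFactors = FALSE)
    }

    partial_units <- Filter(function(u) u$status == "partial", units)
    body_units <- Filter(function(u) u$status != "partial", units)
    if (length(body_units)) body_units <- sample(body_units)

    # partial genes: one contig each, truncated side facing the contig end
    for (u in partial_units) {
      strand <- sample(c("+", "-"), 1L)
      planted <- if (strand == "+") u$seq else revcomp(u$seq)
      m <- sample(0:edge_margin, 1L)
      glen <- nchar(planted)
      left_edge <- (u$cut == "head") == (strand == "+")
      cname <- new_contig_name()
      if (left_edge) {
        fill <- randomDna(contig_length - m - glen, gc)
        contigs[cname] <- paste0(randomDna(m, gc), planted, fill)
        add_row(cname, m, m + glen, strand, u)
      } else {
        fill <- randomDna(contig_length - m - glen, gc)
        contigs[cname] <- paste0(fill, planted, randomDna(m, gc))
        add_row(cname, contig_length - m - glen, contig_length - m, strand, u)
      }
    }

    # full-length genes: packed into shared contigs with random spacers
    i <- 1L
    while (i <= length(body_units)) {
      cname <- new_contig_name()
      parts <- character(0)
      pos <- 0L
      n_in <- 0L
      while (i <= length(body_units) && n_in < genes_per_contig) {
        u <- body_units[[i]]
        strand <- sample(c("+", "-"), 1L)
        # in-frame stop guard flanks the ORF start so flank cannot extend it
        unit <- paste0("TAA", u$seq)
        planted <- if (strand == "+") unit else revcomp(unit)
        spacer <- sample(300:800, 1L)
        if (pos + spacer + nchar(planted) + 100L > contig_length) break
        parts <- c(parts, randomDna(spacer, gc), planted)
        gstart <- pos + spacer + if (strand == "+") 3L else 0L
        add_row(cname, gstart, gstart + nchar(u$seq), strand, u)
        pos <- pos + spacer + nchar(planted)
        n_in <- n_in + 1L
        i <- i + 1L
      }
      parts <- c(parts, randomDna(contig_length - pos, gc))
      contigs[cname] <- paste0(parts, collapse = "")
    }
    if (length(contigs) == 0L)
      contigs[new_contig_name()] <- randomDna(contig_length, gc)

    genomes[[sp]] <- GenomeAssembly(sp, DNAStringSet(contigs))
  }

  ledger <- if (length(ledger_rows)) do.call(rbind, ledger_rows) else
    data.frame(gene_id = character(), species = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), clade = character(),
               true_status = character(), disruptions = character(),
               stringsAsFactors = FALSE)
  list(genomes = genomes, ledger = new("TruthLedger", ledger = ledger))
}

#' Simulate diet codes optionally coupled to repertoire size
#'
#' A continuous latent trait is built as `coupling` times the standardised
#' intact-gene count plus Brownian-motion noise evolved on the tree (per
#' branch variance `noise_sd^2 * len / crown_age`, so the root-to-tip noise
#' variance is `noise_sd^2`). The latent trait is discretised to diet codes
#' `{0, 0.5, 1}` by tertiles; with `coupling = 0` the codes are independent
#' of the counts given the tree.
#'
#' @param tree timed species tree.
#' @param tip_counts named numeric vector of intact-gene counts per tip.
#' @param coupling slope linking standardised counts to the latent trait.
#' @param noise_sd Brownian noise standard deviation at the tips.
#' @param seed integer seed.
#' @return list with `codes` (named vector in \{0, 0.5, 1\}), `latent`, and
#'   `table`, a trait table with species, diet_category, foraging_behaviour
#'   and code columns.
#' @export
simulateTraits <- function(tree, tip_counts, coupling = 0, noise_sd = 1,
                           seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  assertTimedTree(tree)
  set.seed(seed)
  tips <- tree$tip.label
  stopifnot(all(tips %in% names(tip_counts)))
  crown <- max(nodeDepths(tree))
  n_node <- ape::Ntip(tree) + tree$Nnode
  bm <- numeric(n_node)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (i in rev(seq_len(nrow(ord$edge)))) {
    p <- ord$edge[i, 1L]; ch <- ord$edge[i, 2L]
    bm[ch] <- bm[p] + rnorm(1L, 0, noise_sd * sqrt(ord$edge.length[i] / crown))
  }
  x <- tip_counts[tips]
  z <- if (stats::sd(x) > 0) as.numeric(scale(x)) else rep(0, length(x))
  latent <- setNames(coupling * z + bm[seq_along(tips)], tips)
  qs <- quantile(latent, c(1/3, 2/3), names = FALSE, type = 7)
  codes <- setNames(ifelse(latent <= qs[1], 0,
                           ifelse(latent <= qs[2], 0.5, 1)), tips)
  diet <- c("0" = "carnivore", "0.5" = "omnivore", "1" = "herbivore")[
    as.character(codes)]
  foraging <- ifelse(latent >= stats::median(latent), "chew", "swallow_whole")
  tab <- data.frame(species = tips, diet_category = unname(diet),
                    foraging_behaviour = unname(foraging),
                    code = unname(codes), stringsAsFactors = FALSE)
  list(codes = codes, latent = latent, table = tab)
}

#' Write synthetic genomes, ledger, tree and traits to disk
#'
#' One FASTA per species (`<species>.fasta`), the ledger and trait table as
#' TSV, and the species tree as Newick with branch lengths in Myr.
#'
#' @param genomes list of [GenomeAssembly-class] objects.
#' @param ledger a [TruthLedger-class].
#' @param tree species tree.
#' @param traits trait table (`data.frame`) or `NULL`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeSyntheticData <- function(genomes, ledger, tree, traits, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (g in genomes) {
    f <- file.path(dir, paste0(speciesName(g), ".fasta"))
    writeXStringSet(contigSeqs(g), f)
    files <- c(files, f)
  }
  f <- file.path(dir, "truth_ledger.tsv")
  write.table(ledgerTable(ledger), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, f)
  f <- file.path(dir, "species_tree.nwk")
  ape::write.tree(tree, f)
  files <- c(files, f)
  if (!is.null(traits)) {
    f <- file.path(dir, "traits.tsv")
    write.table(traits, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
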