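# Gene model construction and classification: every merged locus becomes
# exactly one of {complete, partial, disrupted}.
#
# Rule set (applied in this order):
#   1. disruption evidence against the clade template (lost start, premature
#      stop, frame-disrupting indel)            -> disrupted
#   2. ORF > 750 bp, starts ATG, ends stop, 7 TM -> complete
#   3. undisrupted and <= 30 bp from a contig end -> partial
#   4. otherwise disrupted, flagged unclassifiable

.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)

#' Count transmembrane segments by sliding-window hydropathy
#'
#' Kyte-Doolittle hydropathy averaged over a sliding window; maximal runs of
#' window positions above `threshold`, separated by at least `min_gap`
#' below-threshold positions, are counted as transmembrane segments. This is
#' a deterministic stand-in for HMM-based TM prediction, and the synthetic
#' clade templates are constructed to show exactly seven segments under the
#' defaults, so the seven-TM completeness check is exercised at the rule
#' level.
#'
#' @param protein amino-acid sequence (character or `AAString`).
#' @param window window size in residues.
#' @param threshold mean hydropathy above which a window is membrane-like.
#' @param min_gap minimal below-threshold run separating two segments.
#' @return integer segment count (0 if the protein is shorter than `window`).
#' @export
countTmSegments <- function(protein, window = 19L, threshold = 1.6,
                            min_gap = 3L) {
  aa <- strsplit(toupper(as.character(protein)), "")[[1]]
  if (length(aa) == 0L) stop("protein must be non-empty")
  if (length(aa) < window) return(0L)
  h <- .KD[aa]
  h[is.na(h)] <- 0
  cs <- c(0, cumsum(h))
  win <- (cs[(window + 1L):length(cs)] - cs[seq_len(length(cs) - window)]) / window
  above <- win > threshold
  r <- rle(above)
  # gaps shorter than min_gap do not split a segment
  if (length(r$lengths) > 2L) {
    interior <- seq(2L, length(r$lengths) - 1L)
    merge_gap <- !r$values[interior] & r$lengths[interior] < min_gap
    r$values[interior][merge_gap] <- TRUE
    above <- inverse.rle(r)
    r <- rle(above)
  }
  sum(r$values)
}

# All complete ORFs (ATG..stop, stop included) in one oriented sequence.
# Returns a data.frame of 1-based inclusive [start, end] coordinates.
.orfScan <- function(s) {
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    starts <- seq(1L + frame, n - 2L, by = 3L)
    if (length(starts) == 0L) next
    codons <- substring(s, starts, starts + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_atg <- codons == "ATG"
    prev_stop <- 0L
    for (i in which(is_stop)) {
      seg <- (prev_stop + 1L):(i - 1L)
      if (length(seg) > 0L && i > prev_stop + 1L) {
        atg <- seg[is_atg[seg]]
        if (length(atg) > 0L) {
          a <- atg[1L]
          out[[length(out) + 1L]] <- c(starts[a], starts[i] + 2L)
        }
      }
      prev_stop <- i
    }
  }
  if (length(out) == 0L)
    return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1L], end = m[, 2L])
}

#' Extract the longest open reading frame over a locus
#'
#' Scans the locus plus `flank` bp on each side, on the locus strand, in all
#' three frames, for the longest complete ORF (ATG through stop codon, stop
#' included) overlapping the locus. Returns `NULL` when no overlapping ORF
#' reaches `floor` bp.
#'
#' @param locus list or one-row data.frame with `start`, `end` (0-based
#'   half-open, forward strand) and `strand`.
#' @param contig_seq contig sequence (character or `DNAString`).
#' @param flank bp of context scanned on each side of the locus.
#' @param floor minimal ORF length reported, bp.
#' @return `list(orf_start, orf_end, cds)` in forward 0-based half-open
#'   coordinates, or `NULL`.
#' @export
extractOrf <- function(locus, contig_seq, flank = 60L, floor = 300L) {
  contig_seq <- as.character(contig_seq)
  L <- nchar(contig_seq)
  if (locus$start < 0L || locus$end > L || locus$start >= locus$end)
    stop("locus outside contig")
  ws <- max(0L, locus$start - flank)
  we <- min(L, locus$end + flank)
  s <- substr(contig_seq, ws + 1L, we)
  if (locus$strand == "-") s <- revcomp(s)
  orfs <- .orfScan(s)
  if (nrow(orfs) == 0L) return(NULL)
  # locus footprint in oriented window coordinates (1-based inclusive)
  if (locus$strand == "+") {
    la <- locus$start - ws + 1L; lb <- locus$end - ws
  } else {
    la <- we - locus$end + 1L; lb <- we - locus$start
  }
  keep <- orfs$end >= la & orfs$start <= lb &
    (orfs$end - orfs$start + 1L) >= floor
  orfs <- orfs[keep, , drop = FALSE]
  if (nrow(orfs) == 0L) return(NULL)
  best <- orfs[which.max(orfs$end - orfs$start), ]
  if (locus$strand == "+") {
    fs <- ws + best$start - 1L; fe <- ws + best$end
  } else {
    fs <- we - best$end; fe <- we - best$start + 1L
  }
  list(orf_start = as.integer(fs), orf_end = as.integer(fe),
       cds = substr(s, best$start, best$end))
}

.DISRUPT_SUBMAT <- NULL

.disruptAlign <- function(template, locus_seq) {
  pairwiseAlignment(DNAString(template), DNAString(locus_seq),
                    type = "overlap",
                    substitutionMatrix =
                      Biostrings::nucleotideSubstitutionMatrix(
                        match = 2, mismatch = -3),
                    gapOpening = 5, gapExtension = 2)
}

#' Detect pseudogenising disruptions against a clade template
#'
#' Aligns the locus sequence to the template with a free-end-gap global
#' alignment (so contig-edge truncation is not penalised or miscalled) and
#' reports: `lost_start` when the template's start codon region (first
#' `start_region` bp) is aligned but carries no in-frame ATG;
#' `premature_stop` when an in-frame stop codon is aligned strictly before
#' the template's final (stop) codon; `frameshift_indel` when any internal
#' gap run has a length not divisible by 3. In-frame indels are not
#' disruptions.
#'
#' @param locus_seq locus sequence oriented to the gene strand.
#' @param template clade reference ORF ([checkTemplate()]).
#' @param start_region bp of the template start searched for an ATG.
#' @return character vector, a subset of
#'   `c("lost_start", "premature_stop", "frameshift_indel")`.
#' @export
detectDisruptions <- function(locus_seq, template, start_region = 30L) {
  template <- as.character(template); locus_seq <- as.character(locus_seq)
  al <- .disruptAlign(template, locus_seq)
  pa <- strsplit(as.character(alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(alignedSubject(al)), "")[[1]]
  tstart <- start(pattern(al))
  tlen <- nchar(template)
  found <- character(0)

  # template position per alignment column (NA at template gaps)
  tp <- tstart - 1L + cumsum(pa != "-")
  tpos <- ifelse(pa != "-", tp, NA_integer_)

  # frameshift: any internal gap run of length not divisible by 3
  gapped <- pa == "-" | sa == "-"
  if (any(gapped)) {
    r <- rle(gapped)
    if (any(r$values & r$lengths %% 3L != 0L))
      found <- c(found, "frameshift_indel")
  }

  # subject codon aligned to each template codon start p (NA if incomplete)
  codon_at <- function(p) {
    cols <- match(c(p, p + 1L, p + 2L), tpos)
    if (anyNA(cols)) return(NA_character_)
    ch <- sa[cols]
    if (any(ch == "-")) return(NA_character_)
    paste(ch, collapse = "")
  }

  # Evaluate the start only when the template start region is represented in
  # the alignment; a locus truncated upstream of the start region (tstart
  # beyond it) is a contig-edge fragment, not a lost start.
  if (tstart <= start_region) {
    inframe <- seq(1L, start_region - 2L, by = 3L)
    cods <- vapply(inframe, codon_at, character(1))
    if (!any(cods == "ATG", na.rm = TRUE))
      found <- c(found, "lost_start")
  }

  n_codons <- tlen %/% 3L
  body <- seq(1L, 3L * (n_codons - 1L) - 2L, by = 3L)
  covered <- body >= tstart
  if (any(covered)) {
    cods <- vapply(body[covered], codon_at, character(1))
    if (any(cods %in% c("TAA", "TAG", "TGA"), na.rm = TRUE))
      found <- c(found, "premature_stop")
  }
  unique(found)
}

#' Classify a merged locus as complete, partial or disrupted
#'
#' Applies the annotation decision order: disruption evidence first, then
#' the complete-gene rule (ORF strictly longer than `min_orf` bp with start
#' and stop codons and exactly `tm_required` transmembrane segments), then
#' the contig-edge partial rule (undisrupted locus within `edge_margin` bp
#' of a contig end, inclusive). Loci failing all three are recorded as
#' disrupted with an `unclassifiable` flag so statuses remain a partition.
#'
#' @param locus list or one-row data.frame with `contig`, `start`, `end`,
#'   `strand` (0-based half-open forward coordinates).
#' @param contig_seq the contig sequence.
#' @param template clade reference ORF used for disruption detection.
#' @param species species id recorded on the model.
#' @param clade clade label recorded on the model.
#' @param min_orf complete-gene ORF length threshold, bp (strict `>`).
#' @param edge_margin partial-gene contig-edge margin, bp (inclusive `<=`).
#' @param flank,orf_floor passed to [extractOrf()].
#' @param tm_required required transmembrane segment count.
#' @param tm_window,tm_threshold,tm_min_gap passed to [countTmSegments()].
#' @return list with `model` (one-row data.frame), `cds`, `protein`.
#' @export
classifyGene <- function(locus, contig_seq, template, species = NA_character_,
                         clade = NA_character_, min_orf = 750L,
                         edge_margin = 30L, flank = 60L, orf_floor = 300L,
                         tm_required = 7L, tm_window = 19L, tm_threshold = 1.6,
                         tm_min_gap = 3L) {
  contig_seq <- as.character(contig_seq)
  L <- nchar(contig_seq)
  locus_seq <- substr(contig_seq, locus$start + 1L, locus$end)
  if (locus$strand == "-") locus_seq <- revcomp(locus_seq)
  edge_distance <- min(locus$start, L - locus$end)

  disr <- detectDisruptions(locus_seq, template)
  orf <- extractOrf(locus, contig_seq, flank = flank, floor = orf_floor)
  cds <- NA_character_; protein <- NA_character_; tm <- NA_integer_
  if (!is.null(orf)) {
    cds <- orf$cds
    protein <- as.character(translate(DNAString(substr(cds, 1L,
                                                       nchar(cds) - 3L))))
    tm <- countTmSegments(protein, window = tm_window,
                          threshold = tm_threshold, min_gap = tm_min_gap)
  }

  if (length(disr) > 0L) {
    status <- "disrupted"
  } else if (!is.null(orf) && nchar(cds) > min_orf && tm == tm_required) {
    status <- "complete"
  } else if (edge_distance <= edge_margin) {
    status <- "partial"
  } else {
    status <- "disrupted"
    disr <- "unclassifiable"
  }

  model <- data.frame(
    gene_id = .geneId(species, locus$contig, locus$start, locus$end,
                      locus$strand),
    species = species, contig = locus$contig, start = locus$start,
    end = locus$end, strand = locus$strand, clade = clade, status = status,
    disruptions = paste(disr, collapse = ","),
    orf_start = if (is.null(orf)) NA_integer_ else orf$orf_start,
    orf_end = if (is.null(orf)) NA_integer_ else orf$orf_end,
    orf_length = if (is.null(orf)) NA_integer_ else nchar(cds),
    tm_count = tm, edge_distance = edge_distance,
    locus_length = locus$end - locus$start,
    stringsAsFactors = FALSE)
  list(model = model, cds = cds, protein = protein)
}

#' Classify all merged loci of one genome
#'
#' Runs [classifyGene()] on every merged locus. The disruption-detection
#' template for a locus is the template named by its best-scoring supporting
#' query when that name is a template, otherwise the template with the
#' highest-scoring free-end-gap alignment to the locus.
#'
#' @param genome a [GenomeAssembly-class].
#' @param loci merged loci ([mergeHits()]).
#' @param templates clade-named `DNAStringSet` of reference ORFs.
#' @param ... parameters passed to [classifyGene()].
#' @return a [GeneModelSet-class].
#' @export
classifyLoci <- function(genome, loci, templates, ...) {
  sp <- speciesName(genome)
  contigs <- contigSeqs(genome)
  rows <- list(); cds <- character(0); prot <- character(0)
  for (i in seq_len(nrow(loci))) {
    locus <- loci[i, ]
    cseq <- as.character(contigs[[locus$contig]])
    cl <- locus$best_query
    if (!(cl %in% names(templates))) {
      ls <- substr(cseq, locus$start + 1L, locus$end)
      if (locus$strand == "-") ls <- revcomp(ls)
      sc <- vapply(seq_along(templates), function(j)
        score(.disruptAlign(as.character(templates[[j]]), ls)), numeric(1))
      cl <- names(templates)[which.max(sc)]
    }
    res <- classifyGene(locus, cseq, as.character(templates[[cl]]),
                        species = sp, clade = cl, ...)
    rows[[i]] <- res$model
    if (!is.na(res$cds)) {
      cds[res$model$gene_id] <- res$cds
      prot[res$model$gene_id] <- res$protein
    }
  }
  models <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(), species = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), clade = character(), status = character(),
               disruptions = character(), orf_start = integer(),
               orf_end = integer(), orf_length = integer(),
               tm_count = integer(), edge_distance = integer(),
               locus_length = integer(), stringsAsFactors = FALSE)
  new("GeneModelSet", models = models,
      cds = DNAStringSet(cds), protein = AAStringSet(prot))
}

#' Summarise a repertoire by status
#'
#' Counts complete, partial and disrupted models per species; intact genes
#' are complete plus partial copies.
#'
#' @param models a [GeneModelSet-class], or a data.frame of models.
#' @return data.frame with `species`, `n_complete`, `n_partial`,
#'   `n_disrupted`, `n_intact`.
#' @export
summarizeRepertoire <- function(models) {
  df <- if (is(models, "GeneModelSet")) modelTable(models) else models
  if (nrow(df) == 0L)
    return(data.frame(species = character(), n_complete = integer(),
                      n_partial = integer(), n_disrupted = integer(),
                      n_intact = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(df, df$species), function(d) {
    data.frame(species = d$species[1L],
               n_complete = sum(d$status == "complete"),
               n_partial = sum(d$status == "partial"),
               n_disrupted = sum(d$status == "disrupted"),
               stringsAsFactors = FALSE)
  }))
  out$n_intact <- out$n_complete + out$n_partial
  rownames(out) <- NULL
  out
}

#' Contig N50 of an assembly
#'
#' The length `L` such that contigs of length at least `L` cover at least
#' half of the total assembly length.
#'
#' @param x a [GenomeAssembly-class] or a numeric vector of contig lengths.
#' @return N50 in bp.
#' @export
contigN50 <- function(x) {
  w <- if (is(x, "GenomeAssembly")) width(contigSeqs(x)) else x
  if (length(w) == 0L) stop("assembly is empty")
  w <- sort(w, decreasing = TRUE)
  w[which(cumsum(w) >= sum(w) / 2)[1L]]
}

#' Assembly-quality guard on contig N50
#'
#' Partial-gene counts become unreliable in fragmented assemblies; the
#' guard flags (but does not exclude) assemblies whose contig N50 is
#' strictly below `min_n50` (default 10 kb).
#'
#' @param assembly a [GenomeAssembly-class].
#' @param min_n50 threshold in bp.
#' @return `list(n50 = <bp>, pass = <logical>)`.
#' @export
assemblyGuard <- function(assembly, min_n50 = 10000L) {
  n50 <- contigN50(assembly)
  list(n50 = n50, pass = n50 >= min_n50)
}

#' Write gene models as GFF3 plus sequence FASTA files
#'
#' One `gene` feature per model with status, clade and disruption reasons in
#' the attributes; coding and protein sequences as FASTA; per-species status
#' counts as TSV.
#'
#' @param gms a [GeneModelSet-class].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return invisibly, the files written.
#' @export
writeGeneModels <- function(gms, dir, prefix = "gene_models") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- modelTable(gms)
  gff <- file.path(dir, paste0(prefix, ".gff3"))
  if (nrow(df) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = df$contig,
      ranges = IRanges(start = df$start + 1L, end = df$end),
      strand = df$strand)
    mcols(gr)$type <- "gene"
    mcols(gr)$ID <- df$gene_id
    mcols(gr)$status <- df$status
    mcols(gr)$clade <- df$clade
    mcols(gr)$disruptions <- ifelse(df$disruptions == "", NA, df$disruptions)
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  fc <- file.path(dir, paste0(prefix, "_cds.fasta"))
  fp <- file.path(dir, paste0(prefix, "_protein.fasta"))
  writeXStringSet(cdsSeqs(gms), fc)
  writeXStringSet(proteinSeqs(gms), fp)
  ft <- file.path(dir, paste0(prefix, "_counts.tsv"))
  write.table(summarizeRepertoire(gms), ft, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(gff, fc, fp, ft))
}
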