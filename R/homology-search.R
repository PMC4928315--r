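# Built-in seed-and-extend homology search. Exact word seeding on both
# strands, diagonal clustering, then gapped extension of each candidate
# window by local alignment; significance via a Karlin-Altschul style
# E-value analog with fixed (documented) lambda and K. Coordinates are
# 0-based half-open on the forward strand throughout; the on-disk tabular
# dialect (1-based inclusive, minus hits with sstart > send) is converted
# at the boundary.

.KA_NT <- c(lambda = 1.28, K = 0.46)   # match +1 / mismatch -2 regime
.KA_AA <- c(lambda = 0.267, K = 0.041) # BLOSUM62 gapped regime

.NT_SUBMAT <- NULL

.ntSubmat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
}

.words <- function(s, w) {
  n <- nchar(s)
  if (n < w) return(character(0))
  substring(s, seq_len(n - w + 1L), seq(w, n))
}

# identity, mismatch, gap-open and length statistics from one string pass
.alnStats <- function(al) {
  pa <- strsplit(as.character(alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(alignedSubject(al)), "")[[1]]
  gp <- pa == "-"; gs <- sa == "-"
  ungapped <- !gp & !gs
  cnt <- function(v) { r <- rle(v); sum(r$values) }
  list(length = length(pa),
       identity = if (any(ungapped)) mean(pa[ungapped] == sa[ungapped]) else 0,
       mismatches = sum(pa[ungapped] != sa[ungapped]),
       gapopen = cnt(gp) + cnt(gs))
}

# Cluster seed matches (qpos, cpos) into candidate windows on one strand.
.seedClusters <- function(qpos, cpos, band, max_jump) {
  d <- cpos - qpos
  o <- order(d, cpos)
  d <- d[o]; cp <- cpos[o]
  cluster <- cumsum(c(TRUE, diff(d) > band))
  out <- list()
  for (cl in split(seq_along(d), cluster)) {
    cp2 <- sort(cp[cl])
    sub <- cumsum(c(TRUE, diff(cp2) > max_jump))
    for (s2 in split(cp2, sub))
      out[[length(out) + 1L]] <- c(range(s2), length(s2))
  }
  out
}

.alignWindow <- function(q_seq, c_seq, wstart, wend, submat, gap_open,
                         gap_extend) {
  win <- substr(c_seq, wstart + 1L, wend)
  al <- pairwiseAlignment(q_seq, win, type = "local",
                          substitutionMatrix = submat,
                          gapOpening = gap_open, gapExtension = gap_extend)
  list(al = al, offset = wstart)
}

.emptyHits <- function() {
  data.frame(query_id = character(), contig = character(), start = integer(),
             end = integer(), strand = character(), qstart = integer(),
             qend = integer(), length = integer(), identity = numeric(),
             mismatches = integer(), gapopen = integer(), score = numeric(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

#' Find candidate receptor loci by seeded local matching
#'
#' Exact `word_size`-mer seeding of each query on both strands of every
#' contig, diagonal clustering of the seeds, and gapped local-alignment
#' extension of each candidate window. A Karlin-Altschul style E-value
#' analog `E = K * m * n * exp(-lambda * S)` (with m the query length, n the
#' total assembly length and fixed nucleotide parameters lambda = 1.28,
#' K = 0.46) filters the hits at `evalue_cutoff`. Minus-strand hits are
#' reported in forward coordinates with `strand = "-"`.
#'
#' @param genome a [GenomeAssembly-class].
#' @param queries named `DNAStringSet` (or character vector) of nucleotide
#'   queries.
#' @param word_size exact-seed length, bp (>= 4).
#' @param evalue_cutoff maximal E-value analog retained.
#' @param band diagonal tolerance when clustering seeds, bp.
#' @param gap_open,gap_extend affine gap penalties of the extension.
#' @param min_seeds minimal exact-word seeds required before a candidate
#'   window is extended.
#' @param pad bp of context added around the seed span before extension.
#' @param seed_ratio within one candidate region, only queries whose seed
#'   count reaches this fraction of the best-seeding query are extended
#'   (a seeding heuristic; set 0 to extend every seeded query).
#' @return a data.frame of hits with 0-based half-open forward coordinates
#'   (`start`, `end`), `strand`, query coordinates (1-based), `identity` in
#'   `[0, 1]`, `score` and `evalue`.
#' @export
findHits <- function(genome, queries, word_size = 11L, evalue_cutoff = 1e-5,
                     band = 24L, gap_open = 5, gap_extend = 2,
                     min_seeds = 2L, pad = 150L, seed_ratio = 0.5) {
  if (word_size < 4L) stop("word_size must be >= 4")
  if (length(queries) == 0L) stop("queries must be non-empty")
  contigs <- contigSeqs(genome)
  if (length(contigs) == 0L) return(.emptyHits())
  qnames <- names(queries)
  if (is.null(qnames)) qnames <- paste0("query", seq_along(queries))
  qseqs <- as.character(queries)
  n_db <- sum(width(contigs))
  submat <- .ntSubmat()
  rows <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[ci]
    cseq <- as.character(contigs[[ci]])
    cw <- .words(cseq, word_size)
    if (length(cw) == 0L) next
    ctab <- split(seq_along(cw), cw)
    for (strand in c("+", "-")) {
      # seed clusters of every query on this contig/strand
      cand <- list()
      for (qi in seq_along(qseqs)) {
        qlen <- nchar(qseqs[qi])
        q_or <- if (strand == "+") qseqs[qi] else revcomp(qseqs[qi])
        qw <- .words(q_or, word_size)
        keep <- qw %in% names(ctab)
        if (!any(keep)) next
        qpos <- which(keep)
        hit_c <- ctab[qw[qpos]]
        qpos <- rep(qpos, lengths(hit_c))
        cpos <- unlist(hit_c, use.names = FALSE)
        for (rg in .seedClusters(qpos, cpos, band, qlen + 200L)) {
          if (rg[3L] < min_seeds) next
          cand[[length(cand) + 1L]] <-
            c(qi = qi, from = rg[1L], to = rg[2L] + word_size - 1L,
              n = rg[3L])
        }
      }
      if (length(cand) == 0L) next
      cm <- do.call(rbind, cand)
      # group overlapping clusters into regions; extend only queries whose
      # seeding is competitive within the region
      reg <- reduce(IRanges(start = cm[, "from"], end = cm[, "to"]),
                    min.gapwidth = 0L)
      for (k in seq_along(reg)) {
        sel <- which(cm[, "from"] <= end(reg)[k] &
                       cm[, "to"] >= start(reg)[k])
        best_n <- max(cm[sel, "n"])
        sel <- sel[cm[sel, "n"] >= seed_ratio * best_n]
        for (s in sel) {
          qi <- cm[s, "qi"]
          qlen <- nchar(qseqs[qi])
          q_or <- if (strand == "+") qseqs[qi] else revcomp(qseqs[qi])
          wstart <- max(0L, cm[s, "from"] - 1L - pad)
          wend <- min(nchar(cseq), cm[s, "to"] + pad)
          aw <- .alignWindow(q_or, cseq, wstart, wend, submat,
                             gap_open, gap_extend)
          al <- aw$al
          S <- score(al)
          if (S <= 0) next
          ev <- .KA_NT["K"] * qlen * n_db * exp(-.KA_NT["lambda"] * S)
          if (ev > evalue_cutoff) next
          s0 <- aw$offset + start(subject(al)) - 1L
          s1 <- aw$offset + end(subject(al))
          p0 <- start(pattern(al)); p1 <- end(pattern(al))
          if (strand == "-") { tmp <- p0; p0 <- qlen - p1 + 1L; p1 <- qlen - tmp + 1L }
          st <- .alnStats(al)
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = qnames[qi], contig = cname, start = s0, end = s1,
            strand = strand, qstart = p0, qend = p1, length = st$length,
            identity = st$identity, mismatches = st$mismatches,
            gapopen = st$gapopen, score = S, evalue = unname(ev),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) return(.emptyHits())
  hits <- do.call(rbind, rows)
  # dedupe identical intervals per query/strand, keeping the best score
  key <- paste(hits$query_id, hits$contig, hits$strand, hits$start, hits$end)
  hits <- hits[order(key, -hits$score), ]
  hits <- hits[!duplicated(paste(hits$query_id, hits$contig, hits$strand,
                                 hits$start, hits$end)), ]
  rownames(hits) <- NULL
  hits
}

#' Translated (protein query) homology search
#'
#' Six-frame translation of every contig, exact amino-acid word seeding, and
#' local-alignment extension with BLOSUM62; the E-value analog uses fixed
#' protein parameters (lambda = 0.267, K = 0.041). Coordinates are mapped
#' back to forward-strand nucleotide space.
#'
#' @param genome a [GenomeAssembly-class].
#' @param queries named `AAStringSet` (or character vector) of protein
#'   queries.
#' @param word_size exact-seed length in residues.
#' @param evalue_cutoff maximal E-value analog retained.
#' @return a data.frame in the same layout as [findHits()] (nucleotide
#'   coordinates).
#' @export
findHitsTranslated <- function(genome, queries, word_size = 4L,
                               evalue_cutoff = 1e-10) {
  if (word_size < 2L) stop("word_size must be >= 2")
  contigs <- contigSeqs(genome)
  if (length(contigs) == 0L) return(.emptyHits())
  qnames <- names(queries)
  if (is.null(qnames)) qnames <- paste0("query", seq_along(queries))
  qseqs <- as.character(queries)
  n_db <- sum(width(contigs)) / 3
  data("BLOSUM62", package = "Biostrings", envir = environment())
  submat <- get("BLOSUM62", envir = environment())
  rows <- list()
  for (ci in seq_along(contigs)) {
    cname <- names(contigs)[ci]
    L <- width(contigs)[ci]
    for (strand in c("+", "-")) {
      cs <- if (strand == "+") contigs[[ci]] else
        reverseComplement(contigs[[ci]])
      for (f in 0:2) {
        aa_len <- (L - f) %/% 3L
        if (aa_len < word_size) next
        aa <- as.character(suppressWarnings(
          translate(subseq(cs, f + 1L, f + 3L * aa_len),
                    if.fuzzy.codon = "X")))
        aa <- gsub("\\*", "X", aa)  # stops break seeds but not translation
        cw <- .words(aa, word_size)
        ctab <- split(seq_along(cw), cw)
        for (qi in seq_along(qseqs)) {
          qlen <- nchar(qseqs[qi])
          qw <- .words(qseqs[qi], word_size)
          keep <- qw %in% names(ctab)
          if (!any(keep)) next
          qpos <- which(keep)
          hit_c <- ctab[qw[qpos]]
          qpos <- rep(qpos, lengths(hit_c))
          cpos <- unlist(hit_c, use.names = FALSE)
          for (rg in .seedClusters(qpos, cpos, 12L, qlen + 60L)) {
            wstart <- max(0L, rg[1L] - 1L - 50L)
            wend <- min(nchar(aa), rg[2L] + word_size - 1L + 50L)
            aw <- .alignWindow(qseqs[qi], aa, wstart, wend, submat, 11, 1)
            al <- aw$al
            S <- score(al)
            if (S <= 0) next
            ev <- .KA_AA["K"] * qlen * n_db * exp(-.KA_AA["lambda"] * S)
            if (ev > evalue_cutoff) next
            a0 <- aw$offset + start(subject(al)) - 1L  # 0-based aa
            a1 <- aw$offset + end(subject(al))
            nt0 <- f + 3L * a0; nt1 <- f + 3L * a1
            if (strand == "-") { tmp <- nt0; nt0 <- L - nt1; nt1 <- L - tmp }
            st <- .alnStats(al)
            rows[[length(rows) + 1L]] <- data.frame(
              query_id = qnames[qi], contig = cname, start = nt0, end = nt1,
              strand = strand, qstart = start(pattern(al)),
              qend = end(pattern(al)), length = st$length,
              identity = st$identity, mismatches = st$mismatches,
              gapopen = st$gapopen, score = S, evalue = unname(ev),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(.emptyHits())
  hits <- do.call(rbind, rows)
  hits <- hits[order(-hits$score), ]
  hits <- hits[!duplicated(paste(hits$query_id, hits$contig, hits$strand,
                                 hits$start, hits$end)), ]
  rownames(hits) <- NULL
  hits
}

#' Discard short hits
#'
#' Retains hits whose subject span is at least `min_length` bp; hits
#' strictly shorter are discarded (the printed rule: outputs of less than
#' 100 bp are dropped). Order is preserved.
#'
#' @param hits a hit data.frame ([findHits()]).
#' @param min_length minimal retained span, bp.
#' @return the filtered data.frame.
#' @export
filterHits <- function(hits, min_length = 100L) {
  hits[(hits$end - hits$start) >= min_length, , drop = FALSE]
}

#' Merge overlapping same-orientation hits into loci
#'
#' Per contig and strand, hit intervals sharing at least one bp are
#' transitively merged into their union. Opposite orientations never merge.
#' The output is ordered by contig then start and the operation is
#' idempotent.
#'
#' @param hits a hit data.frame.
#' @return data.frame of merged loci: `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `n_hits`, `best_query` (query of the
#'   highest-scoring supporting hit), `hit_rows`.
#' @export
mergeHits <- function(hits) {
  if (nrow(hits) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_hits = integer(), best_query = character(),
                      hit_rows = character(), stringsAsFactors = FALSE))
  grp <- paste(hits$contig, hits$strand, sep = "\r")
  out <- list()
  for (g in unique(grp)) {
    idx <- which(grp == g)
    ir <- IRanges(start = hits$start[idx] + 1L, end = hits$end[idx])
    red <- reduce(ir, min.gapwidth = 0L, with.revmap = TRUE)
    rm <- mcols(red)$revmap
    for (k in seq_along(red)) {
      sup <- idx[rm[[k]]]
      best <- sup[which.max(hits$score[sup])]
      out[[length(out) + 1L]] <- data.frame(
        contig = hits$contig[best], start = start(red)[k] - 1L,
        end = end(red)[k], strand = hits$strand[best],
        n_hits = length(sup),
        best_query = hits$query_id[best],
        hit_rows = paste(sup, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  loci <- do.call(rbind, out)
  loci <- loci[order(loci$contig, loci$start, loci$strand), ]
  rownames(loci) <- NULL
  loci
}

#' Iterative self-search expansion of a hit set
#'
#' Uses the subsequences of the current merged loci as new queries against
#' the same genome, repeatedly, until no new merged locus appears or
#' `max_rounds` is reached (the reciprocal-search step, read as expansion:
#' the output is a fixpoint superset of the seed hits). With
#' `mode = "confirm"` no new loci are added; instead seed hits are kept only
#' if they overlap a locus recovered by re-searching with the seed-hit
#' subsequences.
#'
#' @param genome a [GenomeAssembly-class].
#' @param seed_hits hits from [findHits()] against `genome`.
#' @param evalue_cutoff E-value cutoff of the expansion rounds.
#' @param max_rounds maximal number of self-search rounds.
#' @param min_length hit-length filter applied before merging.
#' @param word_size seed word size of the expansion rounds.
#' @param mode `"expand"` (default) or `"confirm"`.
#' @return a hit data.frame (superset of `seed_hits` under `"expand"`).
#' @export
reciprocalExpand <- function(genome, seed_hits, evalue_cutoff = 1e-5,
                             max_rounds = 5L, min_length = 100L,
                             word_size = 11L, mode = c("expand", "confirm")) {
  mode <- match.arg(mode)
  contigs <- contigSeqs(genome)
  lociKey <- function(loci)
    paste(loci$contig, loci$strand, loci$start, loci$end)
  lociSeqs <- function(loci) {
    s <- vapply(seq_len(nrow(loci)), function(i)
      substr(as.character(contigs[[loci$contig[i]]]),
             loci$start[i] + 1L, loci$end[i]), character(1))
    names(s) <- sprintf("rexp|%s:%d-%d", loci$contig, loci$start, loci$end)
    s
  }
  hits <- seed_hits
  loci <- mergeHits(filterHits(hits, min_length))
  if (mode == "confirm") {
    if (nrow(loci) == 0L) return(hits)
    nh <- findHits(genome, lociSeqs(loci), word_size = word_size,
                   evalue_cutoff = evalue_cutoff)
    found <- mergeHits(filterHits(nh, min_length))
    ok <- vapply(seq_len(nrow(hits)), function(i) {
      same <- found$contig == hits$contig[i] & found$strand == hits$strand[i]
      any(same & found$start < hits$end[i] & found$end > hits$start[i])
    }, logical(1))
    return(hits[ok, , drop = FALSE])
  }
  round <- 0L
  while (round < max_rounds && nrow(loci) > 0L) {
    round <- round + 1L
    nh <- findHits(genome, lociSeqs(loci), word_size = word_size,
                   evalue_cutoff = evalue_cutoff)
    if (nrow(nh) > 0L) hits <- rbind(hits, nh)
    new_loci <- mergeHits(filterHits(hits, min_length))
    if (setequal(lociKey(new_loci), lociKey(loci))) break
    loci <- new_loci
  }
  hits <- hits[!duplicated(paste(hits$query_id, hits$contig, hits$strand,
                                 hits$start, hits$end)), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write hits in the 12-column tabular dialect
#'
#' Tab-separated columns query, subject, \%identity, length, mismatches,
#' gap opens, qstart, qend, sstart, send, evalue, bitscore with 1-based
#' inclusive coordinates on disk; minus-strand hits carry sstart > send.
#'
#' @param hits a hit data.frame.
#' @param path output file.
#' @return invisibly `path`.
#' @export
writeHitsTable <- function(hits, path) {
  bits <- (.KA_NT["lambda"] * hits$score - log(.KA_NT["K"])) / log(2)
  sstart <- ifelse(hits$strand == "+", hits$start + 1L, hits$end)
  send <- ifelse(hits$strand == "+", hits$end, hits$start + 1L)
  df <- data.frame(hits$query_id, hits$contig,
                   sprintf("%.2f", 100 * hits$identity), hits$length,
                   hits$mismatches, hits$gapopen, hits$qstart, hits$qend,
                   sstart, send, format(hits$evalue, digits = 3),
                   sprintf("%.1f", bits))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read hits from the 12-column tabular dialect
#'
#' Converts on-disk 1-based inclusive coordinates (minus hits with
#' sstart > send) to internal 0-based half-open forward coordinates. The
#' raw alignment score is reconstructed from the bit score using the fixed
#' nucleotide Karlin-Altschul parameters.
#'
#' @param path tabular hit file (e.g. BLAST `-outfmt 6`).
#' @return a hit data.frame in the internal layout.
#' @export
readHitsTable <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("query_id", "contig", "pident", "length", "mismatches",
                 "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                 "bitscore")
  minus <- df$sstart > df$send
  start0 <- ifelse(minus, df$send, df$sstart) - 1L
  end0 <- ifelse(minus, df$sstart, df$send)
  data.frame(query_id = df$query_id, contig = df$contig, start = start0,
             end = end0, strand = ifelse(minus, "-", "+"),
             qstart = df$qstart, qend = df$qend, length = df$length,
             identity = df$pident / 100, mismatches = df$mismatches,
             gapopen = df$gapopen,
             score = (df$bitscore * log(2) + log(.KA_NT["K"])) /
               .KA_NT["lambda"],
             evalue = as.numeric(df$evalue), stringsAsFactors = FALSE)
}
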