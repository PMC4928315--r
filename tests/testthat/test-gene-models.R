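test_that("transmembrane segments are counted from windowed hydropathy", {
  expect_identical(countTmSegments(strrep("I", 30)), 1L)
  expect_identical(countTmSegments(strrep("D", 100)), 0L)
  expect_identical(countTmSegments(strrep("D", 10)), 0L)  # shorter than window
  expect_error(countTmSegments(""), "non-empty")

  tmpl <- cladeTemplates(12, seed = 201)
  for (i in seq_along(tmpl)) {
    prot <- as.character(Biostrings::translate(Biostrings::subseq(
      tmpl[[i]], 1, 900)))
    expect_identical(countTmSegments(prot), 7L)
  }

  # two hydrophobic runs split only when the gap reaches min_gap
  expect_identical(countTmSegments(paste0(strrep("I", 25), strrep("D", 2),
                                          strrep("I", 25)), min_gap = 3), 1L)
  expect_identical(countTmSegments(paste0(strrep("I", 25), strrep("D", 15),
                                          strrep("I", 25)), min_gap = 3), 2L)
})

test_that("ORF extraction matches exhaustive enumeration and planted truth", {
  tmpl <- as.character(cladeTemplates(1, seed = 202)[[1]])
  set.seed(203)
  contig <- paste0(randomDna(700), "TAA", tmpl, randomDna(700))
  locus <- list(contig = "c1", start = 703L, end = 703L + 903L, strand = "+")
  orf <- extractOrf(locus, contig)
  expect_identical(c(orf$orf_start, orf$orf_end), c(703L, 703L + 903L))
  expect_identical(nchar(orf$cds), 903L)
  expect_identical(orf$cds, tmpl)

  # internal stop truncates the longest recoverable ORF
  ps <- tmpl; substr(ps, 451, 453) <- "TAA"
  contig2 <- paste0(randomDna(700), "TAA", ps, randomDna(700))
  orf2 <- extractOrf(locus, contig2, floor = 100)
  expect_lt(nchar(orf2$cds), 903L)
  expect_identical(orf2$cds, substr(ps, 1, 453))

  # minus strand: same ORF, coordinates mapped to forward space
  contig3 <- paste0(randomDna(700), bitteRep:::revcomp(paste0("TAA", tmpl)),
                    randomDna(700))
  locus3 <- list(contig = "c1", start = 700L, end = 700L + 903L, strand = "-")
  orf3 <- extractOrf(locus3, contig3)
  expect_identical(orf3$cds, tmpl)
  expect_identical(c(orf3$orf_start, orf3$orf_end), c(700L, 1603L))

  # oracle: brute-force enumeration of every ATG..stop span in the window
  set.seed(204)
  for (r in 1:25) {
    win <- randomDna(600)
    locus_r <- list(contig = "c", start = 50L, end = 550L, strand = "+")
    orf_r <- extractOrf(locus_r, win, flank = 50, floor = 30)
    all_orfs <- bruteOrfs(win)
    if (nrow(all_orfs)) {
      all_orfs$len <- all_orfs$end - all_orfs$start + 1L
      overl <- all_orfs[all_orfs$start <= 550 & all_orfs$end >= 51 &
                          all_orfs$len >= 30, ]
    } else overl <- all_orfs
    if (is.null(orf_r)) {
      expect_identical(nrow(overl), 0L)
    } else {
      expect_identical(nchar(orf_r$cds), max(overl$len))
      expect_identical(orf_r$orf_start + 1L,
                       overl$start[which.max(overl$len)])
    }
  }

  expect_error(extractOrf(list(contig = "c", start = -1L, end = 10L,
                               strand = "+"), "ACGT"), "outside")
})

test_that("disruption evidence is read from template alignments", {
  tmpl <- as.character(cladeTemplates(1, seed = 205)[[1]])

  ps <- tmpl; substr(ps, 451, 453) <- "TGA"
  expect_identical(detectDisruptions(ps, tmpl), "premature_stop")

  fs <- paste0(substr(tmpl, 1, 450), substr(tmpl, 453, nchar(tmpl)))
  expect_identical(detectDisruptions(fs, tmpl), "frameshift_indel")

  # in-frame deletion is not a disruption; the translation stays clean
  inframe <- paste0(substr(tmpl, 1, 450), substr(tmpl, 454, nchar(tmpl)))
  expect_identical(detectDisruptions(inframe, tmpl), character(0))
  prot <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(inframe, 1, nchar(inframe) - 3))))
  expect_identical(substr(prot, 1, 1), "M")
  expect_false(grepl("\\*", prot))

  ls <- tmpl; substr(ls, 1, 3) <- "GTG"
  expect_identical(detectDisruptions(ls, tmpl), "lost_start")

  # truncated fragments carry no disruption call from their missing ends
  expect_identical(detectDisruptions(substr(tmpl, 1, 500), tmpl),
                   character(0))
  expect_identical(detectDisruptions(substr(tmpl, 301, 903), tmpl),
                   character(0))
})

test_that("classification applies the printed rules and boundaries", {
  tmpl <- as.character(cladeTemplates(1, seed = 206)[[1]])
  set.seed(207)
  L <- 6000L

  mk <- function(gene, start, len_contig = L) {
    paste0(randomDna(start - 3), "TAA", gene,
           randomDna(len_contig - start - nchar(gene)))
  }

  # complete: 903 bp planted ORF, 7 TM, mid-contig
  ctg <- mk(tmpl, 2000L)
  locus <- list(contig = "c", start = 2000L, end = 2000L + 903L, strand = "+")
  res <- classifyGene(locus, ctg, tmpl, species = "s", clade = "T")
  expect_identical(res$model$status, "complete")
  expect_identical(res$model$tm_count, 7L)
  expect_identical(res$model$orf_length, 903L)

  # disrupted wins over a shorter clean ORF
  ps <- tmpl; substr(ps, 451, 453) <- "TAA"
  ctg2 <- mk(ps, 2000L)
  res2 <- classifyGene(locus, ctg2, tmpl, species = "s", clade = "T")
  expect_identical(res2$model$status, "disrupted")
  expect_identical(res2$model$disruptions, "premature_stop")

  # partial: clean fragment ending 12 bp from the contig end
  frag <- substr(tmpl, 1, 500)
  ctg3 <- paste0(randomDna(L - 500L - 12L), frag, randomDna(12))
  loc3 <- list(contig = "c", start = L - 512L, end = L - 12L, strand = "+")
  res3 <- classifyGene(loc3, ctg3, tmpl, species = "s", clade = "T")
  expect_identical(res3$model$status, "partial")
  expect_identical(res3$model$edge_distance, 12L)

  # the 30 bp margin is inclusive; 31 bp is out
  ctg4 <- paste0(randomDna(L - 500L - 30L), frag, randomDna(30))
  loc4 <- list(contig = "c", start = L - 530L, end = L - 30L, strand = "+")
  expect_identical(classifyGene(loc4, ctg4, tmpl)$model$status, "partial")
  ctg5 <- paste0(randomDna(L - 500L - 31L), frag, randomDna(31))
  loc5 <- list(contig = "c", start = L - 531L, end = L - 31L, strand = "+")
  res5 <- classifyGene(loc5, ctg5, tmpl)
  expect_identical(res5$model$status, "disrupted")
  expect_identical(res5$model$disruptions, "unclassifiable")

  # the complete rule is strict at 750 bp: a 750 bp ORF fails, 753 passes
  orf753 <- sevenTmOrf(30L)
  orf750 <- sevenTmOrf(29L)
  expect_identical(nchar(orf753), 753L)
  expect_identical(nchar(orf750), 750L)
  expect_identical(countTmSegments(sevenTmProtein(30L)), 7L)
  for (orf in list(orf753, orf750)) {
    ctg_o <- mk(orf, 2000L)
    loc_o <- list(contig = "c", start = 2000L, end = 2000L + nchar(orf),
                  strand = "+")
    res_o <- classifyGene(loc_o, ctg_o, orf, species = "s", clade = "T")
    expect_identical(res_o$model$status,
                     if (nchar(orf) > 750) "complete" else "disrupted")
  }
})

test_that("repertoire summaries count the printed categories", {
  df <- data.frame(species = c(rep("a", 10), rep("b", 2)),
                   status = c(rep("complete", 5), rep("partial", 2),
                              rep("disrupted", 3), "complete", "disrupted"),
                   stringsAsFactors = FALSE)
  out <- summarizeRepertoire(df)
  a <- out[out$species == "a", ]
  expect_identical(c(a$n_complete, a$n_partial, a$n_disrupted, a$n_intact),
                   c(5L, 2L, 3L, 7L))
  expect_identical(sum(out$n_complete + out$n_partial + out$n_disrupted),
                   nrow(df))
  expect_identical(nrow(summarizeRepertoire(df[0, ])), 0L)
})

test_that("contig N50 follows the sort-and-accumulate definition", {
  expect_identical(contigN50(c(10, 10, 10)), 10)
  expect_identical(contigN50(c(1, 2, 3, 4, 1000)), 1000)
  set.seed(208)
  for (r in 1:20) {
    w <- sample(1:5000, sample(2:30, 1))
    ws <- sort(w, decreasing = TRUE)
    oracle <- ws[which(cumsum(ws) >= sum(ws) / 2)[1]]
    expect_identical(contigN50(w), oracle)
  }
  g <- GenomeAssembly("s", Biostrings::DNAStringSet(
    c(c1 = strrep("A", 9999))))
  guard <- assemblyGuard(g)
  expect_identical(guard$n50, 9999L)
  expect_false(guard$pass)
  g2 <- GenomeAssembly("s", Biostrings::DNAStringSet(
    c(c1 = strrep("A", 10000))))
  expect_true(assemblyGuard(g2)$pass)
})

test_that("gene models export as GFF3 with status attributes", {
  co <- smallCohort()
  g <- co$genomes[[1]]
  led <- co$ledger[co$ledger$species == speciesName(g), ]
  loci <- data.frame(contig = led$contig, start = led$start, end = led$end,
                     strand = led$strand, best_query = led$clade,
                     stringsAsFactors = FALSE)
  gms <- classifyLoci(g, loci, co$templates)
  dir <- withr::local_tempdir()
  files <- writeGeneModels(gms, dir, prefix = "sp01")
  gff <- rtracklayer::import(files[1])
  expect_identical(length(gff), nrow(modelTable(gms)))
  expect_setequal(gff$status, unique(modelTable(gms)$status))
  expect_identical(GenomicRanges::start(gff) - 1L,
                   modelTable(gms)$start)
  cds <- Biostrings::readDNAStringSet(files[2])
  expect_identical(length(cds), length(cdsSeqs(gms)))
})
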