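test_that("exact planted queries are found with identity 1 on both strands", {
  set.seed(51)
  q <- randomDna(300)
  flank1 <- randomDna(2000); flank2 <- randomDna(1700)
  contig <- paste0(flank1, q, flank2)
  g <- GenomeAssembly("spX", Biostrings::DNAStringSet(c(c1 = contig)))

  h <- findHits(g, c(myq = q))
  expect_identical(nrow(h), 1L)
  expect_identical(h$strand, "+")
  expect_identical(c(h$start, h$end), c(2000L, 2300L))
  expect_equal(h$identity, 1.0)

  contig_rc <- paste0(flank1, bitteRep:::revcomp(q), flank2)
  grc <- GenomeAssembly("spX", Biostrings::DNAStringSet(c(c1 = contig_rc)))
  hrc <- findHits(grc, c(myq = q))
  expect_identical(hrc$strand, "-")
  expect_identical(c(hrc$start, hrc$end), c(2000L, 2300L))
  expect_equal(hrc$identity, 1.0)

  expect_error(findHits(g, c(myq = q), word_size = 3), "word_size")
  empty <- GenomeAssembly("spY", Biostrings::DNAStringSet())
  expect_identical(nrow(findHits(empty, c(myq = q))), 0L)
})

test_that("diverged planted genes are all recovered and match a full local-alignment scan", {
  set.seed(52)
  tmpl <- as.character(cladeTemplates(1, seed = 53)[[1]])
  planted <- data.frame(start = integer(), end = integer())
  contig <- randomDna(1000)
  for (k in 1:10) {
    mut <- mutateSeq(tmpl, 0.05, seed = 530 + k)
    planted <- rbind(planted, data.frame(start = nchar(contig),
                                         end = nchar(contig) + nchar(mut)))
    contig <- paste0(contig, mut, randomDna(1000))
  }
  g <- GenomeAssembly("spZ", Biostrings::DNAStringSet(c(c1 = contig)))
  h <- findHits(g, c(q = tmpl))
  # every planted interval is overlapped by at least one hit
  for (i in 1:10)
    expect_true(any(h$start < planted$end[i] & h$end > planted$start[i]))

  # oracle: unrestricted local alignment of the query against the whole
  # contig recovers the same best interval as the seeded search
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(tmpl), Biostrings::DNAString(contig),
    type = "local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
    gapOpening = 5, gapExtension = 2)
  best <- h[which.max(h$score), ]
  expect_identical(best$start, Biostrings::start(Biostrings::subject(al)) - 1L)
  expect_identical(best$end, Biostrings::end(Biostrings::subject(al)))
  expect_equal(best$score, Biostrings::score(al))
})

test_that("translated search locates a protein query in genomic context", {
  tmpl <- as.character(cladeTemplates(1, seed = 55)[[1]])
  prot <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(tmpl, 1, nchar(tmpl) - 3))))
  set.seed(56)
  contig <- paste0(randomDna(1500), tmpl, randomDna(1500))
  g <- GenomeAssembly("spT", Biostrings::DNAStringSet(c(c1 = contig)))
  h <- findHitsTranslated(g, c(p = prot))
  expect_gt(nrow(h), 0)
  best <- h[which.max(h$score), ]
  expect_identical(c(best$start, best$end), c(1500L, 1500L + 900L))
  # and on the minus strand, mapped back to forward coordinates
  grc <- GenomeAssembly("spT", Biostrings::DNAStringSet(
    c(c1 = bitteRep:::revcomp(contig))))
  hrc <- findHitsTranslated(grc, c(p = prot))
  bestrc <- hrc[which.max(hrc$score), ]
  expect_identical(bestrc$strand, "-")
  expect_identical(c(bestrc$start, bestrc$end),
                   c(nchar(contig) - 2400L, nchar(contig) - 1500L))
})

test_that("short hits are discarded by a strict less-than rule", {
  hits <- data.frame(query_id = "q", contig = "c",
                     start = c(0L, 0L, 0L), end = c(99L, 100L, 101L),
                     strand = "+", score = 1, stringsAsFactors = FALSE)
  kept <- filterHits(hits, 100L)
  expect_identical(kept$end, c(100L, 101L))
  expect_identical(nrow(filterHits(hits[0, ], 100L)), 0L)
})

test_that("merging unions same-orientation overlaps only", {
  hits <- data.frame(
    query_id = c("a", "b", "c"), contig = "c1",
    start = c(10L, 150L, 150L), end = c(200L, 300L, 300L),
    strand = c("+", "+", "-"), score = c(5, 9, 7),
    stringsAsFactors = FALSE)
  loci <- mergeHits(hits)
  expect_identical(nrow(loci), 2L)
  plus <- loci[loci$strand == "+", ]
  expect_identical(c(plus$start, plus$end), c(10L, 300L))
  expect_identical(plus$best_query, "b")
  minus <- loci[loci$strand == "-", ]
  expect_identical(c(minus$start, minus$end), c(150L, 300L))

  # adjacent but non-overlapping intervals stay separate (>= 1 shared bp)
  adj <- data.frame(query_id = c("a", "b"), contig = "c1",
                    start = c(10L, 200L), end = c(200L, 300L), strand = "+",
                    score = 1, stringsAsFactors = FALSE)
  expect_identical(nrow(mergeHits(adj)), 2L)

  # idempotence and permutation invariance against a union-find oracle
  set.seed(61)
  rnd <- data.frame(
    query_id = "q", contig = sample(c("c1", "c2"), 500, TRUE),
    start = sample(0:5000, 500, TRUE), strand = sample(c("+", "-"), 500, TRUE),
    score = runif(500), stringsAsFactors = FALSE)
  rnd$end <- rnd$start + sample(20:400, 500, TRUE)
  m1 <- mergeHits(rnd)
  oracle <- bruteMerge(rnd)
  expect_equal(m1[, c("contig", "strand", "start", "end")][
    order(m1$contig, m1$start, m1$strand), ],
    oracle[order(oracle$contig, oracle$start, oracle$strand),
           c("contig", "strand", "start", "end")],
    ignore_attr = TRUE)
  perm <- rnd[sample(nrow(rnd)), ]
  m2 <- mergeHits(perm)
  expect_identical(m1[, c("contig", "strand", "start", "end")],
                   m2[, c("contig", "strand", "start", "end")])
  again <- mergeHits(data.frame(query_id = m1$best_query, contig = m1$contig,
                                start = m1$start, end = m1$end,
                                strand = m1$strand, score = 1,
                                stringsAsFactors = FALSE))
  expect_identical(again[, c("contig", "start", "end", "strand")],
                   m1[, c("contig", "start", "end", "strand")])
})

test_that("reciprocal expansion reaches paralogs through a similarity chain", {
  tmpl <- as.character(cladeTemplates(1, seed = 71)[[1]])
  b <- mutateSeq(tmpl, 0.20, seed = 72)   # detectable from the query
  c_seq <- mutateSeq(b, 0.20, seed = 73)  # detectable from b only
  set.seed(74)
  contig <- paste0(randomDna(800), b, randomDna(800), c_seq, randomDna(800))
  g <- GenomeAssembly("spR", Biostrings::DNAStringSet(c(c1 = contig)))

  seeds <- findHits(g, c(q = tmpl))
  loci0 <- mergeHits(filterHits(seeds))
  c_start <- 800 + nchar(b) + 800
  expect_false(any(loci0$start < c_start + nchar(c_seq) &
                     loci0$end > c_start))

  expanded <- reciprocalExpand(g, seeds, max_rounds = 3)
  loci1 <- mergeHits(filterHits(expanded))
  expect_true(any(loci1$start < c_start + nchar(c_seq) &
                    loci1$end > c_start))

  expect_identical(reciprocalExpand(g, seeds, max_rounds = 0), seeds)

  # single-locus genome: expansion is a fixpoint at the seed set's loci
  g1 <- GenomeAssembly("spS", Biostrings::DNAStringSet(
    c(c1 = paste0(randomDna(500), tmpl, randomDna(500)))))
  s1 <- findHits(g1, c(q = tmpl))
  e1 <- reciprocalExpand(g1, s1, max_rounds = 5)
  expect_identical(nrow(mergeHits(filterHits(e1))),
                   nrow(mergeHits(filterHits(s1))))
})

test_that("the tabular hit dialect round-trips with 1-based inclusive coordinates", {
  set.seed(81)
  q <- randomDna(400)
  contig <- paste0(randomDna(1000), q, randomDna(500),
                   bitteRep:::revcomp(q), randomDna(300))
  g <- GenomeAssembly("spIO", Biostrings::DNAStringSet(c(c1 = contig)))
  h <- findHits(g, c(q1 = q))
  expect_setequal(unique(h$strand), c("-", "+"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeHitsTable(h, path)
  raw <- read.delim(path, header = FALSE)
  expect_identical(ncol(raw), 12L)
  minus <- raw[raw$V9 > raw$V10, ]
  expect_identical(nrow(minus), sum(h$strand == "-"))
  back <- readHitsTable(path)
  expect_identical(back$start, h$start)
  expect_identical(back$end, h$end)
  expect_identical(back$strand, h$strand)
  expect_equal(back$evalue, h$evalue, tolerance = 1e-2)
})
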