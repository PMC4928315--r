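#' @import methods
#' @importFrom Biostrings DNAStringSet AAStringSet DNAString reverseComplement
#'   translate pairwiseAlignment alignedPattern alignedSubject writeXStringSet
#'   readDNAStringSet width subseq pid nmismatch score pattern subject
#' @importFrom IRanges IRanges reduce start end
#' @importFrom S4Vectors mcols "mcols<-"
#' @importFrom stats rpois rnorm runif quantile cor pt setNames sd median
#' @importFrom utils write.table read.delim head combn data
NULL

#' GenomeAssembly: named contigs for one species
#'
#' A minimal container for one species' genome assembly: a set of named
#' contigs plus the species identifier. Contig N50 (the usual
#' assembly-quality summary) is available through [contigN50()].
#'
#' @slot species single species identifier.
#' @slot contigs a [Biostrings::DNAStringSet] with unique names.
#' @export
setClass("GenomeAssembly",
         representation(species = "character", contigs = "DNAStringSet"))

setValidity("GenomeAssembly", function(object) {
  msg <- NULL
  if (length(object@species) != 1L || is.na(object@species) || !nzchar(object@species))
    msg <- c(msg, "'species' must be a single non-empty string")
  nm <- names(object@contigs)
  if (length(object@contigs) > 0L && (is.null(nm) || anyDuplicated(nm) || any(!nzchar(nm))))
    msg <- c(msg, "contigs must have unique non-empty names")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenomeAssembly
#'
#' @param species species identifier.
#' @param contigs named `DNAStringSet` of contig sequences.
#' @return A [GenomeAssembly-class] object.
#' @export
GenomeAssembly <- function(species, contigs) {
  new("GenomeAssembly", species = as.character(species), contigs = contigs)
}

#' @rdname GenomeAssembly-class
#' @param object,x a `GenomeAssembly`.
#' @export
setGeneric("speciesName", function(x) standardGeneric("speciesName"))
#' @rdname GenomeAssembly-class
#' @export
setMethod("speciesName", "GenomeAssembly", function(x) x@species)

#' @rdname GenomeAssembly-class
#' @export
setGeneric("contigSeqs", function(x) standardGeneric("contigSeqs"))
#' @rdname GenomeAssembly-class
#' @export
setMethod("contigSeqs", "GenomeAssembly", function(x) x@contigs)

setMethod("show", "GenomeAssembly", function(object) {
  w <- width(object@contigs)
  cat("GenomeAssembly for", object@species, "\n")
  cat(" ", length(w), "contig(s),", sum(w), "bp total, N50 =",
      contigN50(object), "bp\n")
})

#' TruthLedger: ground truth for planted synthetic genes
#'
#' Records every receptor gene planted by [plantGenomes()]: its species,
#' contig, 0-based half-open interval on the forward strand, strand, clade
#' label, true status (`complete`, `partial` or `disrupted`) and the
#' disruption kinds carried, if any. Used to validate the annotation rules.
#'
#' @slot ledger a data.frame with columns `gene_id`, `species`, `contig`,
#'   `start`, `end`, `strand`, `clade`, `true_status`, `disruptions`.
#' @export
setClass("TruthLedger", representation(ledger = "data.frame"))

.LEDGER_COLS <- c("gene_id", "species", "contig", "start", "end", "strand",
                  "clade", "true_status", "disruptions")

setValidity("TruthLedger", function(object) {
  df <- object@ledger
  if (!all(.LEDGER_COLS %in% names(df)))
    return(paste("ledger must have columns:", paste(.LEDGER_COLS, collapse = ", ")))
  if (nrow(df) > 0L) {
    if (any(df$start < 0L) || any(df$end <= df$start))
      return("intervals must be 0-based half-open with start >= 0 and end > start")
    if (!all(df$true_status %in% c("complete", "partial", "disrupted")))
      return("true_status must be complete/partial/disrupted")
    if (!all(df$strand %in% c("+", "-")))
      return("strand must be '+' or '-'")
  }
  TRUE
})

#' @rdname TruthLedger-class
#' @param x a `TruthLedger`.
#' @export
setGeneric("ledgerTable", function(x) standardGeneric("ledgerTable"))
#' @rdname TruthLedger-class
#' @export
setMethod("ledgerTable", "TruthLedger", function(x) x@ledger)

setMethod("show", "TruthLedger", function(object) {
  df <- object@ledger
  cat("TruthLedger:", nrow(df), "planted gene(s) in",
      length(unique(df$species)), "species\n")
  if (nrow(df) > 0L) print(table(df$true_status))
})

#' RepertoireHistory: simulated clade gain/loss history on a tree
#'
#' Stores the species tree, the per-node intact copy-number matrix (one row
#' per tree node, one column per clade) and the branch-level event log
#' produced by [evolveRepertoire()]. Gains are duplications of an existing
#' copy; losses are pseudogenisation (which leaves a disrupted copy in the
#' genome) or whole-gene deletion.
#'
#' @slot tree an `ape::phylo` species tree.
#' @slot counts integer matrix, nodes x clades, intact copies per node.
#' @slot events data.frame of events with columns `parent`, `child`,
#'   `clade`, `type` (`gain`, `loss_pseudogene`, `loss_deletion`).
#' @slot clades clade labels (column order of `counts`).
#' @export
setClass("RepertoireHistory",
         representation(tree = "ANY", counts = "matrix",
                        events = "data.frame", clades = "character"))

setValidity("RepertoireHistory", function(object) {
  if (!inherits(object@tree, "phylo")) return("tree must be an ape 'phylo'")
  n_nodes <- object@tree$Nnode + length(object@tree$tip.label)
  if (nrow(object@counts) != n_nodes)
    return("counts must have one row per tree node")
  if (any(object@counts < 0)) return("copy counts must be >= 0")
  if (ncol(object@counts) != length(object@clades))
    return("counts columns must match clade labels")
  TRUE
})

#' @rdname RepertoireHistory-class
#' @param x a `RepertoireHistory`.
#' @export
setGeneric("historyTree", function(x) standardGeneric("historyTree"))
#' @rdname RepertoireHistory-class
#' @export
setMethod("historyTree", "RepertoireHistory", function(x) x@tree)

#' @rdname RepertoireHistory-class
#' @export
setGeneric("nodeCounts", function(x) standardGeneric("nodeCounts"))
#' @rdname RepertoireHistory-class
#' @export
setMethod("nodeCounts", "RepertoireHistory", function(x) x@counts)

#' @rdname RepertoireHistory-class
#' @export
setGeneric("historyEvents", function(x) standardGeneric("historyEvents"))
#' @rdname RepertoireHistory-class
#' @export
setMethod("historyEvents", "RepertoireHistory", function(x) x@events)

#' Per-tip intact copy counts from a RepertoireHistory
#'
#' @param x a `RepertoireHistory`.
#' @return integer matrix, tips x clades.
#' @export
setGeneric("tipCounts", function(x) standardGeneric("tipCounts"))
#' @rdname tipCounts
#' @export
setMethod("tipCounts", "RepertoireHistory", function(x) {
  n_tip <- length(x@tree$tip.label)
  m <- x@counts[seq_len(n_tip), , drop = FALSE]
  rownames(m) <- x@tree$tip.label
  m
})

setMethod("show", "RepertoireHistory", function(object) {
  cat("RepertoireHistory:", length(object@clades), "clades on a",
      length(object@tree$tip.label), "tip tree;",
      nrow(object@events), "event(s)\n")
})

#' GeneModelSet: classified receptor gene models
#'
#' The result of running [classifyLoci()] on one or more genomes: a table of
#' gene models (one row per merged locus) plus the coding and protein
#' sequences of loci with a recoverable ORF. Statuses partition the loci
#' into `complete`, `partial` and `disrupted`.
#'
#' @slot models data.frame with one row per gene model.
#' @slot cds `DNAStringSet` of extracted coding sequences (may be shorter
#'   than `models`; names are gene ids).
#' @slot protein `AAStringSet` of translations (names are gene ids).
#' @export
setClass("GeneModelSet",
         representation(models = "data.frame", cds = "DNAStringSet",
                        protein = "AAStringSet"))

setValidity("GeneModelSet", function(object) {
  need <- c("gene_id", "species", "contig", "start", "end", "strand",
            "status", "disruptions", "tm_count", "edge_distance")
  if (!all(need %in% names(object@models)))
    return(paste("models must have columns:", paste(need, collapse = ", ")))
  if (nrow(object@models) > 0L &&
      !all(object@models$status %in% c("complete", "partial", "disrupted")))
    return("status must be complete/partial/disrupted")
  TRUE
})

#' @rdname GeneModelSet-class
#' @param x a `GeneModelSet`.
#' @export
setGeneric("modelTable", function(x) standardGeneric("modelTable"))
#' @rdname GeneModelSet-class
#' @export
setMethod("modelTable", "GeneModelSet", function(x) x@models)

#' @rdname GeneModelSet-class
#' @export
setGeneric("cdsSeqs", function(x) standardGeneric("cdsSeqs"))
#' @rdname GeneModelSet-class
#' @export
setMethod("cdsSeqs", "GeneModelSet", function(x) x@cds)

#' @rdname GeneModelSet-class
#' @export
setGeneric("proteinSeqs", function(x) standardGeneric("proteinSeqs"))
#' @rdname GeneModelSet-class
#' @export
setMethod("proteinSeqs", "GeneModelSet", function(x) x@protein)

setMethod("show", "GeneModelSet", function(object) {
  cat("GeneModelSet:", nrow(object@models), "gene model(s)\n")
  if (nrow(object@models) > 0L) print(table(object@models$status))
})
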