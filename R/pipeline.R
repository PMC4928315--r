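# Pipeline orchestration: simulate -> search -> classify -> clades ->
# reconstruct -> stats, behind a single config with one global seed fanned
# out to per-stage seeds. Every stage persists its artifacts as plain-text
# files; a rerun with an identical config reproduces them byte-identically.

#' Build a pipeline configuration
#'
#' Returns the default configuration, with any field overridden through
#' `...` (named nested lists are merged field-wise). The defaults carry the
#' pipeline's fixed thresholds: nucleotide / translated E-value cutoffs
#' 1e-5 and 1e-10, the 100 bp hit filter, the 750 bp complete-ORF rule, the
#' 30 bp contig-edge partial margin and the 10 kb N50 guard.
#'
#' @param ... overrides, e.g. `seed = 42`, `simulate = list(n_species = 6)`.
#' @return a config list.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 1L,
    paths = list(out_dir = "bitterep_out", genomes_dir = NULL, tree = NULL,
                 traits = NULL),
    simulate = list(enabled = TRUE, n_species = 8L, crown_age = 80,
                    n_clades = 28L, root_clades = 25L, gain_rate = 0.005,
                    loss_rate = 0.007, contig_length = 12000L,
                    partial_fraction = 0.1, edge_margin = 30L,
                    coupling = 0, noise_sd = 1),
    search = list(word_size = 11L, evalue_nt = 1e-5, evalue_aa = 1e-10,
                  min_hit = 100L, reciprocal_rounds = 1L,
                  reciprocal_mode = "expand"),
    classify = list(min_orf = 750L, edge_margin = 30L, tm_window = 19L,
                    tm_threshold = 1.6, tm_min_gap = 3L, tm_required = 7L,
                    min_n50 = 10000L),
    clades = list(margin_rule = 0.02, distance_ceiling = 0.4,
                  build_tree = FALSE),
    stats = list(schemes = c("main_diet", "foraging"),
                 direction = "positive"))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      for (k in names(over[[nm]])) cfg[[nm]][[k]] <- over[[nm]][[k]]
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Read / write a pipeline configuration
#'
#' YAML (`.yml`/`.yaml`) or JSON by extension; configurations round-trip
#' unchanged.
#'
#' @param path config file.
#' @return the config list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(pipelineConfig, cfg)
}

#' @rdname readPipelineConfig
#' @param config a config list.
#' @export
writePipelineConfig <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(config, path) else
    jsonlite::write_json(config, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(path)
}

.issue <- function(severity, message)
  data.frame(severity = severity, message = message, stringsAsFactors = FALSE)

#' Validate pipeline inputs
#'
#' Checks numeric parameters, FASTA parseability, tree/trait/species label
#' agreement, the bifurcating-tree requirement of the contrasts, and the
#' contig-N50 guard. Issues are returned as data (severity `error` or
#' `warning`), not thrown.
#'
#' @param config a pipeline config ([pipelineConfig()]).
#' @return data.frame of issues (zero rows when fully consistent).
#' @export
validateInputs <- function(config) {
  issues <- list()
  add <- function(sev, msg) issues[[length(issues) + 1L]] <<- .issue(sev, msg)
  num_params <- c(config$search[c("word_size", "evalue_nt", "evalue_aa",
                                  "min_hit")],
                  config$classify[c("min_orf", "edge_margin", "tm_window",
                                    "tm_threshold")])
  for (nm in names(num_params))
    if (!is.numeric(num_params[[nm]]) || num_params[[nm]] <= 0)
      add("error", sprintf("parameter '%s' must be positive", nm))
  if (isTRUE(config$simulate$enabled)) {
    out <- do.call(rbind, issues)
    return(if (is.null(out)) .issue(character(0), character(0))[0, ] else out)
  }
  gd <- config$paths$genomes_dir
  genomes <- list()
  if (is.null(gd) || !dir.exists(gd)) {
    add("error", sprintf("genomes_dir does not exist: %s",
                         if (is.null(gd)) "<unset>" else gd))
  } else {
    fas <- list.files(gd, pattern = "\\.fa(sta)?$", full.names = TRUE)
    if (length(fas) == 0L) add("error", "no FASTA files in genomes_dir")
    for (f in fas) {
      g <- tryCatch(readGenomeFasta(f), error = function(e) NULL)
      if (is.null(g)) { add("error", sprintf("unreadable FASTA: %s", f)); next }
      genomes[[speciesName(g)]] <- g
      guard <- assemblyGuard(g, config$classify$min_n50)
      if (!guard$pass)
        add("warning",
            sprintf("assembly %s has contig N50 %d < %d bp; partial counts may be overestimated",
                    speciesName(g), guard$n50, as.integer(config$classify$min_n50)))
    }
  }
  tree <- NULL
  if (is.null(config$paths$tree) || !file.exists(config$paths$tree)) {
    add("error", sprintf("tree file missing: %s",
                         if (is.null(config$paths$tree)) "<unset>" else
                           config$paths$tree))
  } else {
    tree <- tryCatch(ape::read.tree(config$paths$tree),
                     error = function(e) NULL)
    if (is.null(tree)) add("error", "tree file is not parseable Newick")
    else if (!ape::is.binary(tree))
      add("error", "species tree must be bifurcating for the contrasts")
  }
  if (!is.null(config$paths$traits)) {
    if (!file.exists(config$paths$traits)) {
      add("error", sprintf("trait table missing: %s", config$paths$traits))
    } else if (!is.null(tree)) {
      tb <- read.delim(config$paths$traits, stringsAsFactors = FALSE)
      absent <- setdiff(tree$tip.label, tb$species)
      if (length(absent))
        add("error", sprintf("trait table missing species: %s",
                             paste(absent, collapse = ", ")))
    }
  }
  if (!is.null(tree) && length(genomes) > 0L) {
    absent <- setdiff(tree$tip.label, names(genomes))
    if (length(absent))
      add("error", sprintf("no genome for tree species: %s",
                           paste(absent, collapse = ", ")))
  }
  out <- do.call(rbind, issues)
  if (is.null(out))
    data.frame(severity = character(), message = character(),
               stringsAsFactors = FALSE) else out
}

#' Read one species' genome FASTA
#'
#' The species id is the file name without extension.
#'
#' @param path FASTA file.
#' @return a [GenomeAssembly-class].
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  GenomeAssembly(sub("\\.[^.]*$", "", basename(path)), seqs)
}

#' Run the full repertoire pipeline
#'
#' Executes simulate (optional), search, classify, clades, reconstruct and
#' stats, persisting every intermediate artifact under
#' `config$paths$out_dir` together with a manifest of parameters, seeds and
#' output checksums. Reruns with an identical config reproduce
#' byte-identical text outputs.
#'
#' @param config a pipeline config ([pipelineConfig()]).
#' @param quiet suppress stage messages.
#' @return (invisibly) a report list with the per-stage results.
#' @export
runPipeline <- function(config = pipelineConfig(), quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  out_dir <- config$paths$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  report <- list(config = config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- inputs: simulate or load -------------------------------------------
  templates <- cladeTemplates(
    n_clades = if (isTRUE(config$simulate$enabled))
      config$simulate$n_clades else 28L,
    seed = childSeed(seed, 1L))
  if (isTRUE(config$simulate$enabled)) {
    sim <- config$simulate
    sim_res <- stage("simulate", {
      tree <- simulateTimedTree(sim$n_species, sim$crown_age,
                                seed = childSeed(seed, 2L))
      history <- evolveRepertoire(tree, root_clades = sim$root_clades,
                                  gain_rate = sim$gain_rate,
                                  loss_rate = sim$loss_rate,
                                  clade_labels =
                                    names(templates)[seq_len(sim$root_clades)],
                                  seed = childSeed(seed, 3L))
      planted <- plantGenomes(history, templates,
                              contig_length = sim$contig_length,
                              partial_fraction = sim$partial_fraction,
                              edge_margin = sim$edge_margin,
                              seed = childSeed(seed, 4L))
      intact <- rowSums(tipCounts(history))
      traits <- simulateTraits(tree, intact, coupling = sim$coupling,
                               noise_sd = sim$noise_sd,
                               seed = childSeed(seed, 5L))
      writeSyntheticData(planted$genomes, planted$ledger, tree,
                         traits$table, file.path(out_dir, "simulate"))
      list(tree = tree, history = history, ledger = planted$ledger,
           traits = traits, genomes = planted$genomes)
    })
    report$simulate <- sim_res[c("tree", "history", "ledger", "traits")]
    genomes <- sim_res$genomes
    tree <- sim_res$tree
    trait_table <- sim_res$traits$table
    say("simulate: %d species, %d planted genes", length(genomes),
        nrow(ledgerTable(sim_res$ledger)))
  } else {
    issues <- validateInputs(config)
    if (any(issues$severity == "error"))
      stop("invalid inputs:\n  ",
           paste(issues$message[issues$severity == "error"],
                 collapse = "\n  "), call. = FALSE)
    fas <- list.files(config$paths$genomes_dir, pattern = "\\.fa(sta)?$",
                      full.names = TRUE)
    genomes <- lapply(fas, readGenomeFasta)
    names(genomes) <- vapply(genomes, speciesName, character(1))
    tree <- ape::read.tree(config$paths$tree)
    trait_table <- if (!is.null(config$paths$traits))
      read.delim(config$paths$traits, stringsAsFactors = FALSE) else NULL
  }

  # --- search --------------------------------------------------------------
  search_dir <- file.path(out_dir, "search")
  dir.create(search_dir, showWarnings = FALSE)
  all_loci <- list()
  stage("search", for (sp in names(genomes)) {
    g <- genomes[[sp]]
    hits <- findHits(g, templates, word_size = config$search$word_size,
                     evalue_cutoff = config$search$evalue_nt)
    if (config$search$reciprocal_rounds > 0L)
      hits <- reciprocalExpand(g, hits,
                               evalue_cutoff = config$search$evalue_nt,
                               max_rounds = config$search$reciprocal_rounds,
                               min_length = config$search$min_hit,
                               word_size = config$search$word_size,
                               mode = config$search$reciprocal_mode)
    kept <- filterHits(hits, config$search$min_hit)
    loci <- mergeHits(kept)
    writeHitsTable(hits, file.path(search_dir, paste0(sp, "_hits.tsv")))
    write.table(loci, file.path(search_dir, paste0(sp, "_loci.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    say("search %s: %d hits -> %d >= %d bp -> %d merged loci", sp,
        nrow(hits), nrow(kept), as.integer(config$search$min_hit), nrow(loci))
    all_loci[[sp]] <- loci
  })
  report$loci <- all_loci

  # --- classify ------------------------------------------------------------
  classify_dir <- file.path(out_dir, "classify")
  model_sets <- list()
  guard_flags <- list()
  stage("classify", for (sp in names(genomes)) {
    g <- genomes[[sp]]
    guard <- assemblyGuard(g, config$classify$min_n50)
    if (!guard$pass)
      say("classify %s: WARNING contig N50 %d below %d bp", sp, guard$n50,
          as.integer(config$classify$min_n50))
    guard_flags[[sp]] <- guard
    ms <- classifyLoci(g, all_loci[[sp]], templates,
                       min_orf = config$classify$min_orf,
                       edge_margin = config$classify$edge_margin,
                       tm_required = config$classify$tm_required,
                       tm_window = config$classify$tm_window,
                       tm_threshold = config$classify$tm_threshold,
                       tm_min_gap = config$classify$tm_min_gap)
    writeGeneModels(ms, classify_dir, prefix = sp)
    model_sets[[sp]] <- ms
  })
  models <- do.call(rbind, lapply(model_sets, modelTable))
  rownames(models) <- NULL
  counts <- summarizeRepertoire(models)
  write.table(counts, file.path(classify_dir, "repertoire_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report$models <- model_sets
  report$counts <- counts
  report$assembly_guard <- guard_flags
  say("classify: %d complete, %d partial, %d disrupted",
      sum(counts$n_complete), sum(counts$n_partial), sum(counts$n_disrupted))

  # --- clades --------------------------------------------------------------
  clade_dir <- file.path(out_dir, "clades")
  dir.create(clade_dir, showWarnings = FALSE)
  stage("clades", {
    gene_seqs <- character(0)
    meta <- models
    for (sp in names(genomes)) {
      cs <- contigSeqs(genomes[[sp]])
      df <- modelTable(model_sets[[sp]])
      for (i in seq_len(nrow(df))) {
        s <- substr(as.character(cs[[df$contig[i]]]), df$start[i] + 1L,
                    df$end[i])
        if (df$strand[i] == "-") s <- revcomp(s)
        gene_seqs[df$gene_id[i]] <- s
      }
    }
    asg <- if (length(gene_seqs))
      assignClades(gene_seqs, templates,
                   margin_rule = config$clades$margin_rule,
                   distance_ceiling = config$clades$distance_ceiling,
                   tree = isTRUE(config$clades$build_tree)) else
      list(assignments = data.frame(gene_id = character(),
                                    clade = character()))
    m <- merge(meta, asg$assignments[, c("gene_id", "clade")],
               by = "gene_id", suffixes = c("_template", ""))
    tab <- function(status_sel) {
      sel <- m[m$status %in% status_sel & m$clade != "unassigned", ]
      t0 <- table(factor(sel$species, levels = names(genomes)),
                  factor(sel$clade, levels = names(templates)))
      matrix(as.integer(t0), nrow = nrow(t0), dimnames = dimnames(t0))
    }
    intact_mat <- tab(c("complete", "partial"))
    disrupted_mat <- tab("disrupted")
    write.table(asg$assignments, file.path(clade_dir, "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(species = rownames(intact_mat), intact_mat,
                           check.names = FALSE),
                file.path(clade_dir, "intact_clade_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(species = rownames(disrupted_mat), disrupted_mat,
                           check.names = FALSE),
                file.path(clade_dir, "disrupted_clade_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$clades <- list(assignments = asg$assignments,
                           intact = intact_mat, disrupted = disrupted_mat,
                           tree = asg$tree, monophyly = asg$monophyly)
  })
  say("clades: %d of %d genes assigned",
      sum(report$clades$assignments$clade != "unassigned"),
      nrow(report$clades$assignments))

  # --- reconstruct ---------------------------------------------------------
  stage("reconstruct", {
    anc <- ancestralCounts(tree, report$clades$intact)
    writeBranchEvents(anc, file.path(out_dir, "reconstruct"))
    report$reconstruct <- list(summary = anc,
                                root_bound = rootRepertoireBound(anc))
  })
  say("reconstruct: root repertoire bound = %d clades",
      report$reconstruct$root_bound)

  # --- stats ---------------------------------------------------------------
  if (!is.null(trait_table)) stage("stats", {
    stats_dir <- file.path(out_dir, "stats")
    dir.create(stats_dir, showWarnings = FALSE)
    n_intact <- setNames(report$counts$n_intact, report$counts$species)
    missing_sp <- setdiff(tree$tip.label, names(n_intact))
    n_intact[missing_sp] <- 0L
    rows <- list()
    for (sch in config$stats$schemes) {
      coding <- codeTraits(trait_table, sch)
      res <- tryCatch(
        picAssociation(tree, n_intact, coding,
                       direction = config$stats$direction),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[sch]] <- data.frame(scheme = sch, n_species = res$n_species,
                                n_contrasts = res$n_contrasts, rho = res$rho,
                                p_one_tailed = res$p_one_tailed,
                                slope = res$slope, method = res$method,
                                stringsAsFactors = FALSE)
      say("stats %s: rho = %.3f, one-tailed P = %.4g (n = %d contrasts)",
          sch, res$rho, res$p_one_tailed, res$n_contrasts)
    }
    stats_df <- do.call(rbind, rows)
    rownames(stats_df) <- NULL
    write.table(stats_df, file.path(stats_dir, "associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    report$stats <- stats_df
  })

  # --- manifest ------------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(seed = seed, parameters = config,
                   outputs = as.list(setNames(unname(tools::md5sum(files)),
                                              sub(paste0("^", out_dir, "/?"),
                                                  "", files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  report$manifest <- manifest
  invisible(report)
}
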