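# End-to-end study orchestration: composition -> thermal classification,
# BSR matrix, phylogenetics, motif report, with a run manifest.

#' Build a study configuration
#'
#' Paths and parameters for one full run. All referenced paths are checked
#' up front so a misconfigured study fails before any computation.
#'
#' @param queries Path to the query-enzyme FASTA.
#' @param proteomes Directory of reference proteome FASTAs (one file per
#'   proteome), or NULL to skip the BSR stage.
#' @param msa Path to a pre-aligned FASTA for phylogenetics, or NULL to
#'   skip.
#' @param panels Named character vector of three panel FASTA paths
#'   (names = group labels, e.g. cold/mesophilic/thermophilic), or NULL to
#'   skip the thermal stage.
#' @param q FDR level for the thermal stage (default 0.01).
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param bsr_threshold Homologue call cutoff (default 0.4).
#' @param seed Integer seed for the bootstrap.
#' @param out_dir Output directory (created if missing).
#' @return List of class `study_config`.
#' @export
study_config <- function(queries, proteomes = NULL, msa = NULL,
                         panels = NULL, q = 0.01, bootstrap_reps = 1000,
                         bsr_threshold = 0.4, seed = 1,
                         out_dir = "exoenz_run") {
  for (p in c(queries, msa, panels))
    if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
  if (!is.null(proteomes) && !dir.exists(proteomes))
    stop("missing proteome directory: ", proteomes)
  if (!is.null(panels) &&
      (is.null(names(panels)) || any(!nzchar(names(panels)))))
    stop("panels must be a named vector of FASTA paths")
  stopifnot(q > 0, q < 1, bootstrap_reps >= 1,
            bsr_threshold > 0, bsr_threshold < 1)
  structure(list(queries = queries, proteomes = proteomes, msa = msa,
                 panels = panels, q = q,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 bsr_threshold = bsr_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "study_config")
}

#' Read a key = value study configuration file
#'
#' Plain-text lines `key = value`; `#` comments and blank lines ignored.
#' `panels` is given as comma-separated `label:path` pairs. Unknown keys
#' are an error.
#'
#' @param path Config file path.
#' @param ... Overrides applied after the file is read (flags win).
#' @return A [study_config()].
#' @export
read_study_config <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  args <- setNames(lapply(kv, function(x) trimws(x[2])),
                   vapply(kv, function(x) trimws(x[1]), character(1)))
  known <- names(formals(study_config))
  bad <- setdiff(names(args), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (k in c("q", "bsr_threshold")) if (k %in% names(args))
    args[[k]] <- as.numeric(args[[k]])
  for (k in c("bootstrap_reps", "seed")) if (k %in% names(args))
    args[[k]] <- as.integer(args[[k]])
  if ("panels" %in% names(args)) {
    parts <- strsplit(strsplit(args$panels, ",")[[1]], ":")
    args$panels <- setNames(vapply(parts, function(x) trimws(x[2]),
                                   character(1)),
                            vapply(parts, function(x) trimws(x[1]),
                                   character(1)))
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(study_config, args)
}

.stage <- function(name, out_dir, log, expr) {
  log(paste0("stage ", name, ": start"))
  res <- tryCatch(expr, error = function(e) {
    writeLines(paste("FAILED at stage", name, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  log(paste0("stage ", name, ": done"))
  res
}

#' Run a full comparative study
#'
#' Executes every configured stage — composition and mass table, thermal
#' classification of the queries, BSR matrix against the reference
#' proteomes, NJ phylogeny with bootstrap, motif report — and writes all
#' tab-separated outputs, a Newick tree and a JSON run manifest into the
#' output directory. Outputs are byte-identical across reruns of the same
#' configuration and seed.
#'
#' @param config A [study_config()].
#' @param quiet Suppress console progress messages.
#' @return Invisible list with the in-memory results of each stage and
#'   `files` (paths written).
#' @export
run_study <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "study_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  logfile <- file.path(out, "run.log")
  unlink(logfile)
  log <- function(msg) {
    cat(msg, "\n", file = logfile, append = TRUE, sep = "")
    if (!quiet) message(msg)
  }
  files <- character()
  add <- function(p) files <<- c(files, p)
  results <- list()
  stages <- character()

  queries <- .stage("read_queries", out, log, read_fasta(config$queries))
  stages <- c(stages, "read_queries")

  results$composition <- .stage("composition", out, log, {
    p <- file.path(out, "composition.tsv"); add(p)
    composition_table(queries, path = p)
  })
  stages <- c(stages, "composition")

  if (!is.null(config$panels)) {
    results$thermal <- .stage("thermal", out, log, {
      panels <- lapply(config$panels, function(f)
        composition_matrix(read_fasta(f)))
      model <- fit_thermal_model(panels, q = config$q)
      qc <- composition_matrix(queries)
      cls <- lapply(queries$id, function(id)
        classify_thermal(qc[id, ], model))
      dmat <- do.call(rbind, lapply(cls, function(x) x$distances))
      colnames(dmat) <- paste0("dist_", colnames(dmat))
      ct <- data.frame(id = queries$id,
                       label = vapply(cls, function(x)
                         paste(x$label, collapse = ";"), character(1)),
                       dmat, stringsAsFactors = FALSE)
      p1 <- file.path(out, "thermal_tests.tsv"); add(p1)
      write.table(model$tests, p1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      p2 <- file.path(out, "thermal_centroids.tsv"); add(p2)
      write.table(data.frame(group = rownames(model$centroids),
                             model$centroids, check.names = FALSE),
                  p2, sep = "\t", quote = FALSE, row.names = FALSE)
      p3 <- file.path(out, "thermal_scatter.tsv"); add(p3)
      scatter_table(model, queries = qc, path = p3)
      p4 <- file.path(out, "thermal_classification.tsv"); add(p4)
      write.table(ct, p4, sep = "\t", quote = FALSE, row.names = FALSE)
      list(model = model, classification = ct)
    })
    stages <- c(stages, "thermal")
  }

  if (!is.null(config$proteomes)) {
    results$bsr <- .stage("bsr", out, log, {
      bm <- build_bsr_matrix(queries, config$proteomes,
                             threshold = config$bsr_threshold)
      p1 <- file.path(out, "bsr_matrix.tsv"); add(p1)
      write.table(data.frame(query = rownames(bm$values), bm$values,
                             check.names = FALSE),
                  p1, sep = "\t", quote = FALSE, row.names = FALSE)
      p2 <- file.path(out, "bsr_long.tsv"); add(p2)
      export_heatmap_table(bm, path = p2)
      p3 <- file.path(out, "bsr_calls.tsv"); add(p3)
      write.table(data.frame(query = rownames(bm$calls), bm$calls,
                             check.names = FALSE),
                  p3, sep = "\t", quote = FALSE, row.names = FALSE)
      bm
    })
    stages <- c(stages, "bsr")
  }

  if (!is.null(config$msa)) {
    results$phylo <- .stage("phylo", out, log, {
      block <- read_aligned_fasta(config$msa)
      dm <- p_distance(block)
      p1 <- file.path(out, "p_distances.tsv"); add(p1)
      write_distance_matrix(dm, p1)
      tree <- bootstrap_support(block, n_reps = config$bootstrap_reps,
                                seed = config$seed)
      p2 <- file.path(out, "tree.nwk"); add(p2)
      write_newick(tree, p2)
      tree
    })
    stages <- c(stages, "phylo")
  }

  results$motifs <- .stage("motifs", out, log, {
    p <- file.path(out, "motifs.tsv"); add(p)
    feature_report(queries, path = p)
  })
  stages <- c(stages, "motifs")

  manifest <- list(package = "exoenz",
                   version = as.character(packageVersion("exoenz")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   seed = config$seed,
                   config = unclass(config),
                   stages = stages,
                   outputs = basename(files))
  mp <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  log("run complete")
  invisible(c(results, list(files = c(files, mp))))
}
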