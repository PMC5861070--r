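# End-to-end orchestration: filter -> tree -> conservation -> dnds -> nls
# -> pI -> stats, with a provenance manifest tying outputs to inputs,
# parameters and seed.

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order and writes all stage outputs
#' plus a `manifest.json` (package version, seed, parameters, md5 checksums
#' of inputs and outputs) to `out_dir`.  A stage failure aborts with an
#' error naming the stage.
#'
#' @param config either a path to a JSON file or a list with elements:
#'   \describe{
#'     \item{proteins}{path to the aligned protein FASTA (required)}
#'     \item{cds}{path to the aligned in-frame CDS FASTA (for the dnds
#'       stage)}
#'     \item{metadata}{path to the metadata TSV (required)}
#'     \item{partition}{path to the domain-partition JSON (required for
#'       conservation/dnds/pi)}
#'     \item{seed}{integer seed (default 1)}
#'     \item{bootstrap_reps}{bootstrap replicates (default 100)}
#'     \item{collapse}{support collapse threshold in percent (default 50)}
#'     \item{dnds_group}{metadata `group` whose members enter the dN/dS
#'       analysis (default: the largest group)}
#'     \item{nls_region}{optional `c(start, end)` scan window}
#'     \item{stats_table}{optional path to a long-format TSV
#'       (species/protein/domain/value) for the factorial stage}
#'   }
#' @param out_dir output directory (created).
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  for (need in c("proteins", "metadata"))
    if (is.null(config[[need]]))
      stop("config error: missing required entry '", need, "'")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  reps <- if (is.null(config$bootstrap_reps)) 100L
          else as.integer(config$bootstrap_reps)
  collapse <- if (is.null(config$collapse)) 50 else config$collapse
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done (%.2fs)", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  outputs <- character()
  emit <- function(x, file) {
    path <- file.path(out_dir, file)
    if (is.data.frame(x)) write_tsv(x, path) else x(path)
    outputs <<- c(outputs, path)
    path
  }

  aln <- stage("load", {
    a <- read_fasta(config$proteins, type = "AA")
    md <- read_metadata(config$metadata)
    join_metadata(a, md)   # errors on unresolvable ids
    list(aln = a, md = md)
  })
  md <- aln$md; prot <- aln$aln
  partition <- if (!is.null(config$partition))
    stage("partition", read_partition(config$partition)) else NULL

  tree <- stage("tree", {
    filtered <- complete_deletion(prot)
    emit(data.frame(filtered_column = seq_along(attr(filtered, "retained")),
                    source_column = attr(filtered, "retained")),
         "tree_columns.tsv")
    tr <- bootstrap_supports(filtered, n_reps = reps, seed = seed,
                             collapse = collapse)
    emit(function(p) write_newick(tr, p), "tree.nwk")
    tr
  })

  profile <- stage("conservation", {
    kept <- modal_gap_deletion(prot)
    ref <- if (!is.null(partition)) partition$reference else NULL
    pr <- site_conservation(kept, reference = ref, source = prot)
    emit(as.data.frame(pr), "conservation_profile.tsv")
    if (!is.null(partition)) {
      emit(domain_summary(pr, partition), "domain_summary.tsv")
      emit(heatmap_table(pr, partition), "heatmap_values.tsv")
    }
    pr
  })

  if (!is.null(config$cds) && !is.null(partition)) {
    stage("dnds", {
      cds <- read_fasta(config$cds, type = "DNA")
      grp <- config$dnds_group
      if (is.null(grp))
        grp <- names(sort(table(md$group), decreasing = TRUE))[1L]
      ids <- md$id[md$group == grp]
      if (length(ids) < 2L)
        stop("group '", grp, "' has fewer than 2 members")
      emit(as.data.frame(group_domain_dnds(cds, partition, ids)),
           "dnds.tsv")
    })
  }

  stage("nls", {
    region <- config$nls_region
    emit(nls_table(prot, region = region), "nls_candidates.tsv")
  })

  if (!is.null(partition)) {
    stage("pi", emit(domain_pi(prot, partition), "isoelectric_points.tsv"))
  }

  if (!is.null(config$stats_table)) {
    stage("stats", {
      tab <- utils::read.delim(config$stats_table)
      fit <- fit_factorial(tab)
      emit(fit$contrasts, "contrasts.tsv")
      emit(fit$terms, "model_terms.tsv")
    })
  }

  manifest <- stage("manifest", {
    inputs <- unlist(config[intersect(
      c("proteins", "cds", "metadata", "partition", "stats_table"),
      names(config))])
    man <- list(
      package = "il1evol",
      version = as.character(utils::packageVersion("il1evol")),
      seed = seed, bootstrap_reps = reps, collapse = collapse,
      inputs = as.list(tools::md5sum(inputs)),
      outputs = as.list(tools::md5sum(outputs)))
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
    man
  })
  invisible(manifest)
}
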