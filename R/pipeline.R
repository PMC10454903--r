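#' Configuration for an end-to-end pipeline run
#'
#' Each data stream comes from exactly one source: the protein stream from
#' a proteinGroups TSV (`proteins = list(file = ...)`) or from simulation
#' (`proteins = list(simulate = list(...))`, arguments passed to
#' [cohort_sim_config()]); the deformability stream from a per-sample CSV
#' (`deformability = list(file = ...)`) or from the simulated cohort
#' (`deformability = list(from_simulation = TRUE)`). An optional imaging
#' stream (`images = list(simulate = list(n_samples = , fields_per_sample
#' = , ...))`, arguments passed to [image_sim_config()]) renders and
#' measures ground-truth fields, producing the per-cell table. A seed is
#' mandatory whenever anything is simulated; every module draws from its
#' own named substream of it (see [substream_seed()]), so outputs are
#' byte-reproducible.
#'
#' @param output_dir directory for the report bundle (created if needed).
#' @param proteins,deformability,images stream sources, see above.
#' @param seed integer master seed.
#' @param p_threshold screen selection cutoff (default 0.005).
#' @param group_threshold grouping cutoff on mean off-diagonal r
#'   (default 0.775).
#' @param udfc_threshold,ldfc_threshold ER cutoffs (defaults 1.1, 1.3).
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir, proteins,
                       deformability = list(from_simulation = TRUE),
                       images = NULL, seed = NULL,
                       p_threshold = 0.005, group_threshold = 0.775,
                       udfc_threshold = 1.1, ldfc_threshold = 1.3) {
  one_source <- function(x, allowed, stream) {
    got <- intersect(names(x), allowed)
    if (length(got) != 1) {
      stop(stream, " stream must have exactly one source of {",
           paste(allowed, collapse = ", "), "}; got {",
           paste(names(x), collapse = ", "), "}")
    }
    got
  }
  psrc <- one_source(proteins, c("file", "simulate"), "proteins")
  dsrc <- one_source(deformability, c("file", "from_simulation"),
                     "deformability")
  isrc <- if (!is.null(images)) one_source(images, "simulate", "images")
  if (dsrc == "from_simulation" && psrc != "simulate") {
    stop("deformability can only come from_simulation when proteins are simulated")
  }
  simulating <- psrc == "simulate" || !is.null(isrc)
  if (simulating && is.null(seed)) {
    stop("seed is mandatory when any stream is simulated")
  }
  structure(list(output_dir = output_dir, proteins = proteins,
                 deformability = deformability, images = images,
                 seed = seed, p_threshold = p_threshold,
                 group_threshold = group_threshold,
                 udfc_threshold = udfc_threshold,
                 ldfc_threshold = ldfc_threshold),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror the arguments of [run_config()].
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the full deformability-proteomics pipeline
#'
#' Orchestrates the analysis from inputs (real or simulated) to the report
#' bundle: `cells.csv` (per-cell measurements, when an imaging stream is
#' present), `sample_stats.csv` (per-sample deformability parameters),
#' `screen.csv` (per-protein correlation screen), `matrix.csv`
#' (inter-correlation matrix of selected proteins), `groups.csv` (group
#' split), `model.json` (best cross-group two-protein model with its
#' search log), and `run_log.yaml` (package version, seed, thresholds and
#' filter counts). Re-running with the same configuration and seed
#' reproduces every file byte for byte.
#'
#' @param config a [run_config()] (or path to a YAML accepted by
#'   [read_run_config()]).
#' @return Invisibly, a list with the in-memory results (`table`, `aer`,
#'   `screen`, `matrix`, `split`, `pair`, `files`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## protein + deformability streams
  sim <- NULL
  tab <- stage("proteins", {
    if (!is.null(config$proteins$simulate)) {
      args <- config$proteins$simulate
      args$seed <- substream_seed(config$seed, "cohort")
      sim <- simulate_cohort(do.call(cohort_sim_config, args))
      write_protein_groups(sim$table, out("proteins.tsv"))
      sim$table
    } else {
      read_protein_groups(config$proteins$file,
                          config$proteins$sample_map)
    }
  })
  aer <- stage("deformability", {
    if (isTRUE(config$deformability$from_simulation)) {
      write_aer_csv(sim, out("aer.csv"))
      sim$aer
    } else {
      read_aer_csv(config$deformability$file)
    }
  })

  ## optional imaging stream: render + measure ground-truth fields
  if (!is.null(config$images)) {
    stage("images", {
      iargs <- config$images$simulate
      n_img_samples <- iargs$n_samples %||% 2
      n_fields <- iargs$fields_per_sample %||% 1
      iargs$n_samples <- NULL; iargs$fields_per_sample <- NULL
      all_cells <- list(); stats <- list()
      for (s in seq_len(n_img_samples)) {
        fields <- lapply(seq_len(n_fields), function(f) {
          iargs$seed <- substream_seed(config$seed,
                                       sprintf("images/%d/%d", s, f))
          render_field(do.call(image_sim_config, iargs))$image
        })
        res <- analyze_sample(fields,
                              udfc_threshold = config$udfc_threshold,
                              ldfc_threshold = config$ldfc_threshold)
        cells <- res$cells
        cells <- cbind(sample = sprintf("IMG%02d", s), cells)
        all_cells[[s]] <- cells
        stats[[s]] <- cbind(sample = sprintf("IMG%02d", s),
                            as.data.frame(res$distribution))
      }
      write.csv(do.call(rbind, all_cells), out("cells.csv"),
                row.names = FALSE)
      write.csv(do.call(rbind, stats), out("sample_stats.csv"),
                row.names = FALSE)
    })
  } else {
    # deformability known only at sample level
    write.csv(data.frame(sample = names(aer), n_cells = NA_integer_,
                         aer = unname(aer), mer = NA_real_,
                         pct_udfc = NA_real_, pct_ldfc = NA_real_,
                         cv = NA_real_),
              out("sample_stats.csv"), row.names = FALSE)
  }

  ## screen, grouping, model
  scr <- stage("screen", screen_proteins(tab, aer, config$p_threshold))
  write.csv(scr, out("screen.csv"), row.names = FALSE)
  selected <- scr$gene[scr$selected]
  cm <- NULL; split <- NULL; pair <- NULL
  if (length(selected) >= 2) {
    cm <- stage("correlation_matrix", correlation_matrix(tab, selected))
    write.csv(data.frame(gene = rownames(cm), cm, check.names = FALSE),
              out("matrix.csv"), row.names = FALSE)
    split <- stage("grouping", split_groups(cm, config$group_threshold))
    write.csv(data.frame(gene = names(split$statistic),
                         mean_offdiag_r = unname(split$statistic),
                         group = ifelse(names(split$statistic) %in%
                                          split$group1, 1L, 2L)),
              out("groups.csv"), row.names = FALSE)
  }
  model_out <- stage("model", {
    if (!is.null(split) && length(split$group1) && length(split$group2)) {
      pair <- select_pair(tab, aer, split)
      list(type = "two_parameter_cross_group",
           genes = pair$model$genes,
           coefficients = as.list(pair$model$coefficients),
           intercept = pair$model$intercept,
           diagnostics = pair$model$diagnostics,
           search_log = pair$log)
    } else if (length(selected) >= 1) {
      fit <- fit_linear(tab, aer, selected[1])
      list(type = "one_parameter_top_gene",
           genes = fit$genes,
           coefficients = as.list(fit$coefficients),
           intercept = fit$intercept,
           diagnostics = fit$diagnostics)
    } else {
      list(type = "none", note = "no proteins passed the screen")
    }
  })
  jsonlite::write_json(model_out, out("model.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  ## run log: everything needed to reproduce the bundle (no timestamps,
  ## so identical runs are byte-identical)
  yaml::write_yaml(list(
    package = "erythroflex",
    version = as.character(packageVersion("erythroflex")),
    seed = config$seed,
    thresholds = list(p_threshold = config$p_threshold,
                      group_threshold = config$group_threshold,
                      udfc = config$udfc_threshold,
                      ldfc = config$ldfc_threshold),
    proteins = if (!is.null(config$proteins$simulate)) "simulated" else config$proteins$file,
    n_samples = length(aer),
    n_proteins = length(tab$gene_symbols),
    n_selected = length(selected),
    filter_log = as.list(tab$provenance$filter_log)
  ), out("run_log.yaml"))

  invisible(list(table = tab, aer = aer, screen = scr, matrix = cm,
                 split = split, pair = pair, model = model_out,
                 files = list.files(config$output_dir)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
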