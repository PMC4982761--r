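#' Validate and resolve a pipeline configuration
#'
#' Accepts a YAML file path or a nested list. Exactly one of `simulation`
#' (arguments for [sim_config()]) or `inputs` (paths to an annotation and
#' tag files) must be present. Unknown keys anywhere are rejected, and
#' every default is filled into the resolved copy, so the resolved
#' configuration fully determines a run.
#'
#' Defaults: window 5000 bp, bin 50 bp, fold thresholds 1.4 / 0.5,
#' read-through expression floor 0.5 FPKM, metagene flank 3000 bp.
#'
#' @param config Path to a YAML file, or a list.
#' @return A resolved `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  allowed <- c("simulation", "inputs", "conditions", "classifier",
               "window_bp", "profiles", "stats", "seed")
  unknown <- setdiff(names(config), allowed)
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  has_sim <- !is.null(config$simulation)
  has_inp <- !is.null(config$inputs)
  if (has_sim == has_inp) {
    stop("exactly one of 'simulation' or 'inputs' must be present")
  }
  seed <- as.integer(config$seed %||% 1L)
  window_bp <- as.numeric(config$window_bp %||% 5000)
  if (window_bp <= 0) stop("window_bp must be > 0")

  if (has_sim) {
    sim_args <- config$simulation
    bad <- setdiff(names(sim_args), names(formals(sim_config)))
    if (length(bad)) stop("unknown simulation key(s): ",
                          paste(bad, collapse = ", "))
    sim_args$seed <- seed
    sim <- do.call(sim_config, sim_args)
    conditions <- sim$conditions
  } else {
    inp <- config$inputs
    bad <- setdiff(names(inp), c("annotation", "dialect", "tags",
                                 "chrom_length"))
    if (length(bad)) stop("unknown inputs key(s): ",
                          paste(bad, collapse = ", "))
    if (is.null(inp$annotation) || is.null(inp$tags)) {
      stop("inputs must give 'annotation' and 'tags'")
    }
    sim <- NULL
    conditions <- unique(vapply(inp$tags, function(t)
      as.character(t$condition), character(1)))
  }
  cond_pair <- as.character(config$conditions %||% conditions)
  if (length(cond_pair) != 2L) stop("need exactly two conditions")
  if (!all(cond_pair %in% conditions)) {
    stop("condition label not found: ",
         paste(setdiff(cond_pair, conditions), collapse = ", "))
  }

  cls_args <- config$classifier %||% list()
  bad <- setdiff(names(cls_args), names(formals(classifier_config)))
  if (length(bad)) stop("unknown classifier key(s): ",
                        paste(bad, collapse = ", "))
  cls_args$window_bp <- window_bp
  cls <- do.call(classifier_config, cls_args)

  profiles <- config$profiles %||% list(
    list(anchor = "TTS", upstream_bp = 1000, downstream_bp = 5000,
         bin_bp = 50),
    list(anchor = "scaled-body", upstream_bp = 3000,
         downstream_bp = 3000, bin_bp = 50, body_bins = 60))
  profiles <- lapply(profiles, function(p) {
    bad <- setdiff(names(p), names(formals(profile_spec)))
    if (length(bad)) stop("unknown profile key(s): ",
                          paste(bad, collapse = ", "))
    do.call(profile_spec, p)
  })

  stats_args <- config$stats %||% list()
  bad <- setdiff(names(stats_args), "ks_mode")
  if (length(bad)) stop("unknown stats key(s): ",
                        paste(bad, collapse = ", "))
  ks_mode <- match.arg(stats_args$ks_mode %||% "profile",
                       c("profile", "per_gene"))

  structure(list(simulation = sim,
                 inputs = if (has_inp) config$inputs else NULL,
                 conditions = cond_pair, classifier = cls,
                 window_bp = window_bp, profiles = profiles,
                 ks_mode = ks_mode, seed = seed),
            class = "pipeline_config")
}

profile_label <- function(spec) {
  if (spec$anchor == "scaled-body") "scaled" else tolower(spec$anchor)
}

#' Run the full read-through analysis pipeline
#'
#' Stages, in fixed order: obtain data (simulate, or load the configured
#' annotation and tag files), quantify body and read-through FPKM,
#' classify read-through changes between the two conditions, build the
#' configured metagene profiles per condition (replicate-averaged), and
#' compare the two conditions' downstream profiles with the two-sample
#' Kolmogorov-Smirnov test. All intermediates are written as
#' tab-separated tables under `out_dir`; the run report (with an md5
#' manifest) is written last. Deterministic given (config, seed).
#'
#' @param config A `pipeline_config`, list, or YAML path (see
#'   [validate_config()]).
#' @param out_dir Output directory (created).
#' @param quiet Suppress stage messages.
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(out_dir, "RUN_INCOMPLETE")
  file.create(marker)
  say <- function(stage, ...) if (!quiet) {
    message("[", stage, "] ", ...)
  }
  stage_wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- data ------------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    sim <- stage_wrap("simulate", simulate_experiment(cfg$simulation))
    stage_wrap("simulate", write_simulation(sim, out_dir))
    models <- sim$models; libraries <- sim$libraries
    chrom_length <- cfg$simulation$chrom_length
    say("simulate", length(models), " genes, ", length(libraries),
        " libraries")
  } else {
    inp <- cfg$inputs
    models <- stage_wrap("load", read_gene_models(
      inp$annotation, dialect = inp$dialect %||% "BED12"))
    libraries <- stage_wrap("load", lapply(inp$tags, function(t) {
      load_stranded_tags(t$path, t$condition, t$replicate,
                         library_size = t$library_size %||% NULL)
    }))
    names(libraries) <- vapply(libraries, function(l)
      paste0(l$condition, "_", l$replicate), character(1))
    chrom_length <- inp$chrom_length %||% NULL
    say("load", length(models), " genes, ", length(libraries),
        " libraries")
  }

  # -- quantify --------------------------------------------------------
  quants <- stage_wrap("quantify", quantify_all(
    models, libraries, window_bp = cfg$window_bp,
    chrom_length = chrom_length))
  data.table::fwrite(quants, file.path(out_dir, "quant.tsv"), sep = "\t")
  say("quantify", nrow(quants), " gene x library rows")

  # -- classify --------------------------------------------------------
  calls <- stage_wrap("classify", classify_all(
    models, quants, control = cfg$conditions[1L],
    treatment = cfg$conditions[2L], config = cfg$classifier,
    chrom_length = chrom_length))
  data.table::fwrite(calls, file.path(out_dir, "calls.tsv"), sep = "\t")
  call_summary <- as.list(table(factor(
    calls$call, levels = c("up", "down", "unchanged", "excluded_overlap",
                           "excluded_low"))))
  call_summary <- lapply(call_summary, as.integer)
  say("classify", paste(names(call_summary), unlist(call_summary),
                        sep = "=", collapse = ", "))

  # -- metagene --------------------------------------------------------
  analyzed <- calls$gene_id[calls$call %in% c("up", "down", "unchanged")]
  prof_genes <- if (length(analyzed) >= 2L) {
    models[vapply(models, `[[`, character(1), "gene_id") %in% analyzed]
  } else models
  profile_files <- character(0)
  profiles_by_cond <- list()
  for (spec in cfg$profiles) {
    lab <- profile_label(spec)
    for (cond in cfg$conditions) {
      libs <- Filter(function(l) l$condition == cond, libraries)
      per_rep <- lapply(libs, function(l) {
        stage_wrap("metagene", if (spec$anchor == "scaled-body") {
          suppressWarnings(scaled_metagene(prof_genes, l, spec,
                                           chrom_length))
        } else {
          average_profile(prof_genes, l, spec, chrom_length)
        })
      })
      vals <- rowMeans(do.call(cbind, lapply(per_rep, `[[`, "values")))
      prof <- per_rep[[1L]]
      tab <- data.table::data.table(
        bin = seq_along(vals), offset = prof$offsets, mean = vals,
        n_genes = prof$n_genes)
      f <- file.path(out_dir, paste0("profile_", lab, "_", cond, ".tsv"))
      data.table::fwrite(tab, f, sep = "\t")
      profile_files <- c(profile_files, f)
      profiles_by_cond[[lab]][[cond]] <- list(values = vals,
                                              offsets = prof$offsets)
    }
    say("metagene", lab, " profiles written for both conditions")
  }

  # -- stats -----------------------------------------------------------
  ks <- NULL
  if (cfg$ks_mode == "profile") {
    tts <- profiles_by_cond[["tts"]]
    if (!is.null(tts)) {
      dn1 <- tts[[cfg$conditions[1L]]]
      dn2 <- tts[[cfg$conditions[2L]]]
      keep <- dn1$offsets >= 0
      ks <- stage_wrap("stats",
                       ks_two_sample(dn1$values[keep], dn2$values[keep]))
    }
  } else {
    cm <- condition_means(quants)
    cm <- cm[cm$gene_id %in% calls$gene_id[
      calls$call %in% c("up", "down", "unchanged")], ]
    ks <- stage_wrap("stats", ks_two_sample(
      cm$mean_rt_fpkm[cm$condition == cfg$conditions[1L]],
      cm$mean_rt_fpkm[cm$condition == cfg$conditions[2L]]))
  }
  if (!is.null(ks)) say("stats", "KS D = ", signif(ks$statistic, 4),
                        ", p = ", signif(ks$p_value, 4))

  # -- report ----------------------------------------------------------
  files <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                        c(marker, file.path(out_dir, "report.json"))))
  manifest <- lapply(files, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  report <- list(
    package_version = as.character(utils::packageVersion("readthru")),
    seed = cfg$seed,
    conditions = cfg$conditions,
    ks_mode = cfg$ks_mode,
    n_genes = length(models),
    n_libraries = length(libraries),
    quant_rows = nrow(quants),
    call_summary = call_summary,
    ks = if (is.null(ks)) NULL else
      list(D = ks$statistic, p = ks$p_value, n1 = ks$n1, n2 = ks$n2),
    manifest = manifest)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  unlink(marker)
  say("report", "written to ", file.path(out_dir, "report.json"))
  invisible(report)
}
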