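#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' every stage parameter at its default. Supply overrides as a nested list
#' (or a YAML file of the same shape) and they are merged over these
#' defaults.
#'
#' @return A named list of stage parameters.
#' @export
pipeline_config <- function() {
  list(
    outdir = "n2opart_out",
    input_dir = NULL,
    simulate = list(scenario = "default", seed = 1L),
    stages = c("simulate", "fluxes", "partition", "q10", "community", "qpcr"),
    partition = list(mode = "paired", B = 1000L, mc_sd = 0.25, seed = 101L,
                     alpha = 0.05, p_adjust = "none"),
    q10 = list(day0 = "constant", B = 1000L, seed = 202L),
    community = list(min_len = 50, bin_width = 2, occurrence = 0.02,
                     min_height = 0, permutations = 999L, seed = 303L),
    qpcr = list(elution_volume_uL = 100, dilution = 20,
                template_volume_uL = 2, extraction_mass_g = 0.5,
                moisture = 0, ntc_cutoff = 35)
  )
}

#' Run the full partitioning pipeline
#'
#' Orchestrates simulate (optional) -> flux conversion -> acetylene
#' partitioning + bootstrap -> Q10 fitting -> community statistics -> qPCR
#' quantification. Each stage's outputs are written as CSV under
#' `config$outdir` and fed to the next stage; a `manifest.json` records
#' package version, parameters, seeds and MD5 checksums of every output. A
#' failing stage aborts with the stage named; outputs of completed stages
#' are retained.
#'
#' @param config A nested list of overrides over [pipeline_config()], or a
#'   path to a YAML file with the same structure.
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  warnings_log <- character(0)

  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    message("[n2opart] stage: ", name)
    withCallingHandlers(
      tryCatch(fun(), error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        warnings_log <<- c(warnings_log, paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    )
  }
  emit <- function(obj, name) {
    readr::write_csv(obj, file.path(cfg$outdir, name))
  }

  res$study <- stage("simulate", function() {
    sc <- switch(cfg$simulate$scenario,
                 default = scenario_default(),
                 null = scenario_null(),
                 stop("unknown scenario: ", cfg$simulate$scenario))
    study <- generate_study(sc, seed = cfg$simulate$seed)
    write_study(study, cfg$outdir)
    study
  })

  in_dir <- if (is.null(res$study)) cfg$input_dir else cfg$outdir
  res$rates <- stage("fluxes", function() {
    gas <- read_gas(file.path(in_dir, "gas.csv"))
    rates <- flux_rates(gas)
    emit(rates, "rates.csv")
    rates
  })

  res$partition <- stage("partition", function() {
    pc <- cfg$partition
    campaign <- res$rates[res$rates$day %in%
                            unique(res$rates$day[res$rates$c2h2_level != "P0"]), ]
    cells <- partition_rates(campaign, mode = pc$mode)
    emit(cells, "process_rates.csv")
    boot <- bootstrap_partition(campaign, "gross_production", B = pc$B,
                                mc_sd = pc$mc_sd, seed = pc$seed,
                                alpha = pc$alpha, p_adjust = pc$p_adjust)
    emit(boot$estimates, "bootstrap.csv")
    emit(boot$comparisons, "bootstrap_comparisons.csv")
    list(cells = cells, bootstrap = boot)
  })

  res$q10 <- stage("q10", function() {
    net <- res$rates[res$rates$c2h2_level == "P0" &
                       res$rates$arm == "net_monitoring", ]
    cum <- net |>
      dplyr::group_by(.data$fertilization, .data$temperature_C, .data$replicate) |>
      dplyr::summarise(
        cumulative_ngN_g = cumulative_emission(.data$day, .data$rate_ngN_g_d,
                                               day0 = cfg$q10$day0),
        .groups = "drop"
      )
    emit(cum, "cumulative.csv")
    fits <- cum |>
      dplyr::group_by(.data$fertilization) |>
      dplyr::group_modify(function(d, key) {
        f <- q10_by_replicate(d)
        tibble::tibble(alpha = f$pooled$alpha, beta = f$pooled$beta,
                       q10 = f$pooled$q10, r_squared = f$pooled$r_squared,
                       q10_mean_replicates = mean(f$per_replicate$q10))
      }) |>
      dplyr::ungroup()
    emit(fits, "q10.csv")
    ferts <- unique(cum$fertilization)
    cmp <- list()
    if (length(ferts) > 1L) {
      prs <- utils::combn(ferts, 2L)
      for (k in seq_len(ncol(prs))) {
        a <- cum[cum$fertilization == prs[1L, k], ]
        b <- cum[cum$fertilization == prs[2L, k], ]
        cc <- compare_q10(a, b, B = cfg$q10$B, seed = cfg$q10$seed + k)
        cmp[[k]] <- tibble::tibble(
          group_a = prs[1L, k], group_b = prs[2L, k],
          q10_a = cc$q10_a, q10_b = cc$q10_b, difference = cc$difference,
          lower = cc$lower, upper = cc$upper, p = cc$p
        )
      }
    }
    comparisons <- dplyr::bind_rows(cmp)
    if (nrow(comparisons)) emit(comparisons, "q10_comparisons.csv")
    list(cumulative = cum, fits = fits, comparisons = comparisons)
  })

  res$community <- stage("community", function() {
    cc <- cfg$community
    out <- list()
    perm_rows <- list()
    mantel_rows <- list()
    for (gene in c("nosZI", "nosZII")) {
      path <- file.path(in_dir, paste0("peaks_", gene, ".csv"))
      if (!file.exists(path)) next
      peaks <- read_peaks(path)
      mat <- process_peaks(peaks, cc$min_len, cc$bin_width, cc$occurrence,
                           cc$min_height)
      emit(tibble::as_tibble(mat, rownames = "sample_id"),
           paste0("community_", gene, ".csv"))
      meta <- sample_metadata(rownames(mat))
      keep <- !is.na(meta$temperature_C)
      mat_i <- mat[keep, , drop = FALSE]
      meta_i <- meta[keep, , drop = FALSE]
      meta_f <- meta_i
      meta_f$day <- factor(meta_f$day)
      meta_f$temperature_C <- factor(meta_f$temperature_C)
      d <- bray_curtis(mat_i)
      emit(tibble::as_tibble(as.matrix(d), rownames = "sample_id"),
           paste0("distances_", gene, ".csv"))
      pa <- permanova(d, meta_f, c("day", "fertilization", "temperature_C"),
                      permutations = cc$permutations, seed = cc$seed)
      pa$gene <- gene
      perm_rows[[gene]] <- pa
      # Mantel: community structure vs gross rates within fertilization
      if (!is.null(res$partition)) {
        cells <- res$partition$cells
        for (fert in unique(meta_i$fertilization)) {
          sub <- meta_i$fertilization == fert
          if (sum(sub) < 5L) next
          md <- dplyr::left_join(
            meta_i[sub, ], cells,
            by = c("fertilization", "temperature_C", "day")
          )
          for (item in c("production", "consumption", "net")) {
            dr <- stats::dist(md[[item]])
            mt <- mantel_test(stats::as.dist(as.matrix(d)[sub, sub]), dr,
                              permutations = cc$permutations, seed = cc$seed)
            mantel_rows[[length(mantel_rows) + 1L]] <- tibble::tibble(
              gene = gene, fertilization = fert, item = item,
              r = mt$r, p = mt$p, permutations = mt$permutations
            )
          }
        }
      }
      out[[gene]] <- list(matrix = mat, distances = d)
    }
    permanova_tbl <- dplyr::bind_rows(perm_rows)
    if (nrow(permanova_tbl)) emit(permanova_tbl, "permanova.csv")
    mantel_tbl <- dplyr::bind_rows(mantel_rows)
    if (nrow(mantel_tbl)) emit(mantel_tbl, "mantel.csv")
    c(out, list(permanova = permanova_tbl, mantel = mantel_tbl))
  })

  res$qpcr <- stage("qpcr", function() {
    qc <- cfg$qpcr
    std_path <- file.path(in_dir, "standards.csv")
    q_path <- file.path(in_dir, "qpcr.csv")
    if (!file.exists(std_path) || !file.exists(q_path)) return(NULL)
    standards <- read_standards(std_path)
    curves <- lapply(split(standards, standards$gene), function(s) {
      fit_standard_curve(s$log10_copies, s$cq)
    })
    qdat <- read_qpcr(q_path)
    ab <- summarise_abundance(qdat, curves, qc$elution_volume_uL,
                              qc$dilution, qc$template_volume_uL,
                              qc$extraction_mass_g, qc$moisture,
                              qc$ntc_cutoff)
    ab <- dplyr::bind_cols(ab, sample_metadata(ab$sample_id)[
      c("fertilization", "temperature_C", "day")])
    emit(ab, "abundance.csv")
    cors <- list()
    if (!is.null(res$partition)) {
      cells <- res$partition$cells
      cell_ab <- ab |>
        dplyr::filter(!is.na(.data$temperature_C)) |>
        dplyr::group_by(.data$gene, .data$fertilization, .data$temperature_C,
                        .data$day) |>
        dplyr::summarise(copies_per_g = mean(.data$copies_per_g), .groups = "drop") |>
        dplyr::inner_join(cells, by = c("fertilization", "temperature_C", "day"))
      for (gene in unique(cell_ab$gene)) {
        sub <- cell_ab[cell_ab$gene == gene, ]
        for (item in c("production", "consumption", "net")) {
          ct <- correlate_rates(log10(sub$copies_per_g), sub[[item]])
          cors[[length(cors) + 1L]] <- tibble::tibble(
            gene = gene, item = item, r = ct$r, p = ct$p, n = ct$n
          )
        }
      }
    }
    cors <- dplyr::bind_rows(cors)
    if (nrow(cors)) emit(cors, "abundance_correlations.csv")
    list(curves = curves, abundance = ab, correlations = cors)
  })

  files <- sort(list.files(cfg$outdir, pattern = "\\.csv$", full.names = TRUE))
  sums <- tools::md5sum(files)
  manifest <- list(
    package = "n2opart",
    version = as.character(utils::packageVersion("n2opart")),
    config = cfg,
    warnings = warnings_log,
    files = as.list(setNames(unname(sums), basename(files))),
    manifest_hash = unname(tools::md5sum(
      tempfile_with(paste(basename(files), unname(sums), collapse = "\n"))
    ))
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# write a string to a temp file and return its path (for hashing)
tempfile_with <- function(text) {
  path <- tempfile()
  writeLines(text, path)
  path
}

#' Parse the sample ids emitted by the study generator
#'
#' Sample ids have the form `<fert>_T<temp>_d<day>_r<rep>` (or `_pre_` for
#' pre-incubation day-0 samples with no temperature assignment).
#'
#' @param sample_id Character vector of sample ids.
#' @return A tibble with `sample_id`, `fertilization`, `temperature_C`,
#'   `day`, `replicate`.
#' @export
sample_metadata <- function(sample_id) {
  parts <- strsplit(sample_id, "_", fixed = TRUE)
  tibble::tibble(
    sample_id = sample_id,
    fertilization = vapply(parts, `[`, "", 1L),
    temperature_C = vapply(parts, function(p) {
      if (p[2L] == "pre") NA_real_ else as.numeric(sub("^T", "", p[2L]))
    }, numeric(1)),
    day = vapply(parts, function(p) as.numeric(sub("^d", "", p[3L])), numeric(1)),
    replicate = vapply(parts, function(p) as.integer(sub("^r", "", p[4L])), integer(1))
  )
}
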