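#' Pipeline configuration
#'
#' Collects the simulation configuration, stage toggles, and
#' discovery/replication split settings for [run_pipeline()].
#'
#' @param sim A [sim_config()] describing the cohort to generate.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("glm", "fc", "actflow", "selectivity", "dominance", "nulls",
#'   "stats")`. Later stages require their prerequisites.
#' @param fc_method `"combinedfc"` (estimate per participant from rest) or
#'   `"truth"` (use the ground-truth weights).
#' @param n_perm Permutations for the max-T stage.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Seed for the discovery/replication split and permutations.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            stages = c("glm", "fc", "actflow", "selectivity",
                                       "dominance", "nulls", "stats"),
                            fc_method = c("combinedfc", "truth"),
                            n_perm = 1000,
                            out_dir = NULL,
                            seed = sim$seed) {
  known <- c("glm", "fc", "actflow", "selectivity", "dominance", "nulls",
             "stats")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(sim = sim, stages = stages,
                 fc_method = match.arg(fc_method),
                 n_perm = n_perm, out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

need <- function(stage, have, requires) {
  if (stage %in% have && !all(requires %in% have))
    stop("stage '", stage, "' requires: ",
         paste(setdiff(requires, have), collapse = ", "))
}

analyse_half <- function(idx, dataset, rest, config) {
  cfg <- config$sim
  model <- dataset$model
  stages <- config$stages
  cx_names <- names(model$complexes)
  cxu <- complex_units(model)
  out <- list(participants = idx)

  if ("glm" %in% stages) {
    out$betas <- lapply(idx, function(p)
      estimate_betas(dataset$task_bold[[p]], dataset$design_matrix))
  }
  if ("fc" %in% stages) {
    out$fc <- lapply(idx, function(p) {
      if (config$fc_method == "truth") model$weights
      else combinedfc(rest[[p]])$weights
    })
  }
  if ("actflow" %in% stages) {
    out$mapped <- lapply(seq_along(idx), function(i)
      map_activity(out$betas[[i]], out$fc[[i]], targets = cxu)$mapped)
    out$accuracy <- accuracy(
      lapply(out$betas, function(b) b[cxu, , drop = FALSE]),
      out$mapped)
  }
  if ("selectivity" %in% stages) {
    tab <- do.call(rbind, lapply(cx_names, function(cx) {
      units <- model$complexes[[cx]]$units
      rows <- match(units, cxu)
      cat_c <- cfg$category_conditions[[cx]]
      non_c <- setdiff(unlist(cfg$category_conditions), cat_c)
      do.call(rbind, lapply(seq_along(idx), function(i) {
        s <- complex_selectivity(out$betas[[i]][units, , drop = FALSE],
                                 out$mapped[[i]][rows, , drop = FALSE],
                                 cat_c, non_c)
        data.frame(participant = idx[i], complex = cx,
                   actual = s$actual_selectivity,
                   mapped = s$mapped_selectivity,
                   contribution_pct = s$contribution_pct)
      }))
    }))
    tab$outlier <- FALSE
    for (cx in cx_names) {
      rows <- tab$complex == cx
      tab$outlier[rows] <- remove_outliers(tab$contribution_pct[rows])$flags
    }
    out$selectivity <- tab
  }
  if ("dominance" %in% stages) {
    out$dominance <- lapply(cx_names, function(cx) {
      units <- model$complexes[[cx]]$units
      per_part <- lapply(seq_along(idx), function(i) {
        comps <- network_restricted_maps(out$betas[[i]], out$fc[[i]],
                                         model$partition, targets = units)
        profiles <- vapply(comps, colMeans, numeric(cfg$n_conditions))
        dominance(profiles, colMeans(out$betas[[i]][units, , drop = FALSE]))
      })
      list(
        complex = cx,
        full_r2 = mean(vapply(per_part, `[[`, numeric(1), "full_r2")),
        partial_r2 = rowMeans(vapply(per_part, `[[`,
                                     numeric(length(NETWORK_LABELS)),
                                     "partial_r2")))
    })
    names(out$dominance) <- cx_names
  }
  if ("nulls" %in% stages) {
    out$nulls <- do.call(rbind, lapply(cx_names, function(cx) {
      units <- model$complexes[[cx]]$units
      cat_c <- cfg$category_conditions[[cx]]
      non_c <- setdiff(unlist(cfg$category_conditions), cat_c)
      do.call(rbind, lapply(setdiff(cx_names, cx), function(donor) {
        vals <- vapply(seq_along(idx), function(i) {
          Wn <- substitute_fingerprint(out$fc[[i]], units,
                                       model$complexes[[donor]]$units)
          m <- map_activity(out$betas[[i]], Wn, targets = units)$mapped
          complex_selectivity(out$betas[[i]][units, , drop = FALSE], m,
                              cat_c, non_c)$mapped_selectivity
        }, numeric(1))
        data.frame(complex = cx, donor = donor,
                   null_mapped_selectivity = mean(vals))
      }))
    }))
  }
  if ("stats" %in% stages) {
    keep <- !out$selectivity$outlier
    sel_mat <- do.call(cbind, lapply(cx_names, function(cx)
      out$selectivity$mapped[out$selectivity$complex == cx & keep][
        seq_len(min(table(out$selectivity$complex[keep])))]))
    colnames(sel_mat) <- cx_names
    ctr_mat <- do.call(cbind, lapply(cx_names, function(cx)
      out$selectivity$contribution_pct[
        out$selectivity$complex == cx & keep][
          seq_len(min(table(out$selectivity$complex[keep])))]))
    colnames(ctr_mat) <- cx_names
    out$stats <- list(
      selectivity_gt_1 = maxt_test(sel_mat, mu0 = 1, n_perm = config$n_perm,
                                   seed = config$seed + 11L),
      contribution_gt_50 = maxt_test(ctr_mat, mu0 = 50,
                                     n_perm = config$n_perm,
                                     seed = config$seed + 12L))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, splits participants into discovery and
#' replication halves (random halves under the config seed), and runs the
#' enabled stages — GLM activation estimation, resting-state FC, fully
#' distributed activity-flow mapping of the functional complexes, category
#' selectivity with distributed-contribution estimates and outlier flags,
#' per-network dominance analysis, fingerprint-substitution nulls, and max-T
#' group inference — identically but independently on each half.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result` with `model`, `discovery`,
#'   `replication`, `config`; written as TSV/JSON plus a text summary when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  need("fc", st, character(0)); need("actflow", st, c("glm", "fc"))
  need("selectivity", st, "actflow"); need("dominance", st, c("glm", "fc"))
  need("nulls", st, c("glm", "fc", "actflow", "selectivity"))
  need("stats", st, "selectivity")

  cfg <- config$sim
  model <- generate_ground_truth(cfg)
  rest <- if ("fc" %in% st && config$fc_method == "combinedfc")
    simulate_rest(model, cfg) else NULL
  dataset <- simulate_task(model, cfg)

  set.seed(config$seed + 100L)
  np <- cfg$n_participants
  disc <- sort(sample.int(np, np %/% 2))
  repl <- setdiff(seq_len(np), disc)

  result <- structure(list(
    model = model,
    discovery = analyse_half(disc, dataset, rest, config),
    replication = analyse_half(repl, dataset, rest, config),
    config = config
  ), class = "pipeline_result")

  if (!is.null(config$out_dir)) write_pipeline_report(result, config$out_dir)
  result
}

write_pipeline_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg_json <- jsonlite::toJSON(unclass(result$config$sim), auto_unbox = TRUE,
                               digits = NA)
  cfg_hash <- sum(utf8ToInt(as.character(cfg_json)) *
                    (seq_len(nchar(cfg_json)) %% 97 + 1))
  lines <- c("activity-flow selectivity pipeline report",
             sprintf("config hash: %d  seed: %d", cfg_hash,
                     result$config$seed), "")
  for (half in c("discovery", "replication")) {
    h <- result[[half]]
    if (!is.null(h$selectivity)) {
      utils::write.table(h$selectivity,
                         file.path(dir, paste0(half, "_selectivity.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      agg <- stats::aggregate(
        cbind(actual, mapped, contribution_pct) ~ complex,
        data = h$selectivity[!h$selectivity$outlier, ], FUN = mean)
      lines <- c(lines, paste0("[", half, "] group means (outliers removed):"),
                 utils::capture.output(print(agg, row.names = FALSE)), "")
    }
    if (!is.null(h$nulls)) {
      utils::write.table(h$nulls, file.path(dir, paste0(half, "_nulls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      lines <- c(lines,
                 paste0("[", half, "] fingerprint-substitution nulls written"))
    }
    if (!is.null(h$stats)) {
      sj <- list(
        selectivity_gt_1 = h$stats$selectivity_gt_1[
          c("observed", "threshold", "p_corrected", "n_perm", "seed")],
        contribution_gt_50 = h$stats$contribution_gt_50[
          c("observed", "threshold", "p_corrected", "n_perm", "seed")])
      jsonlite::write_json(sj, file.path(dir, paste0(half, "_stats.json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  if (!is.null(result$discovery$selectivity) &&
      !is.null(result$replication$selectivity)) {
    d <- result$discovery$selectivity; r <- result$replication$selectivity
    lines <- c(lines, sprintf(
      "half agreement: mean |contribution difference| = %.2f points",
      abs(mean(d$contribution_pct[!d$outlier]) -
            mean(r$contribution_pct[!r$outlier]))))
  }
  writeLines(lines, file.path(dir, "report.txt"))
  invisible(dir)
}
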