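#' Flatten statistical results into a reporting table
#'
#' @param results Named list of [stat_result()] objects.
#' @return data.frame with `analysis`, `test`, `term`, `statistic`, `df1`,
#'   `df2`, `epsilon`, `p` (one row per term), mirroring the usual
#'   figure-legend reporting style.
#' @export
stats_table <- function(results) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    cbind(data.frame(analysis = nm, test = r$test), r$terms)
  })
  do.call(rbind, rows)
}

#' Run configuration for end-to-end experiments
#'
#' @param mode `"synthetic"` (generate, analyze, test) or `"source_data"`
#'   (load long-format summary tables and run the recipes' tests; touches no
#'   random stream).
#' @param seed Master seed for synthetic mode.
#' @param sim A [sim_config()] (synthetic mode).
#' @param n_animals Photometry animals per condition (synthetic mode).
#' @param n_cells Cells per group and protocol (synthetic mode).
#' @param n_subjects Preference-test subjects per arm (synthetic mode).
#' @param recipes Source-data mode: list of recipes, each
#'   `list(name=, path=, test=, ...)` with `test` one of `paired_t`,
#'   `unpaired_t`, `rm_anova_gg`, `mixed_anova`, `two_way_anova`,
#'   `kruskal_wallis` and the remaining entries passed to that function.
#'   Recipes are data, so adding a figure is an addition, not a code edit.
#' @param out_dir Optional output directory for CSV reports.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "source_data"), seed = 1L,
                       sim = sim_config(seed = seed), n_animals = 7,
                       n_cells = 8, n_subjects = 8, recipes = list(),
                       out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "source_data" && !length(recipes)) {
    stop("source_data mode requires at least one recipe (table + test)")
  }
  structure(list(mode = mode, seed = seed, sim = sim, n_animals = n_animals,
                 n_cells = n_cells, n_subjects = n_subjects,
                 recipes = recipes, out_dir = out_dir),
            class = "run_config")
}

#' Photometry experiment: sessions, summaries, repeated-measures test
#'
#' Generates one session per animal and stimulus for the given day, runs
#' the full bout-response pipeline on each, and tests the per-animal
#' stimulus means with the GG-corrected one-way repeated-measures ANOVA.
#'
#' @param sim A [sim_config()].
#' @param n_animals Number of animals.
#' @param day `"day3"` or `"day7"`.
#' @param stimuli Stimulus labels (default: names of `sim$transient_amp`).
#' @return List with `summaries` (per animal x stimulus data.frame),
#'   `anova` (a [stat_result()]), and `n_bouts_excluded`.
#' @export
run_photometry_experiment <- function(sim, n_animals = 7, day = "day7",
                                      stimuli = names(sim$transient_amp)) {
  rows <- list()
  excluded <- 0L
  for (a in seq_len(n_animals)) {
    aid <- sprintf("animal%02d", a)
    for (s in stimuli) {
      ses <- generate_photometry_session(sim, paste0(day, "_", s), aid)
      res <- analyze_photometry_session(ses)
      excluded <- excluded + sum(!res$bouts$included)
      rows[[length(rows) + 1L]] <- res$summary
    }
  }
  summaries <- do.call(rbind, rows)
  long <- data.frame(subject = summaries$animal_id,
                     condition = summaries$stimulus,
                     value = summaries$mean_dff)
  list(summaries = summaries,
       anova = rm_anova_gg(long),
       n_bouts_excluded = excluded)
}

#' Preference experiment: trials per arm, group x treatment tests
#'
#' Generates `n_subjects` trials per arm, scores each with
#' [preference_ratio()], and tests side-by-side partner time with the
#' Type III two-way ANOVA (virus group x drug treatment) plus a
#' Kruskal-Wallis comparison of partner vs stranger side-by-side times
#' within each treatment.
#'
#' @param sim A [sim_config()].
#' @param n_subjects Subjects per arm.
#' @param arms Character vector of `"<virus>_<drug>"` arms.
#' @return List with `trials` (scored data.frame), `anova_sbs`,
#'   `kruskal_cno`.
#' @export
run_preference_experiment <- function(sim, n_subjects = 8,
                                      arms = c("Gq_CNO", "Gq_saline",
                                               "Gi_CNO", "Gi_saline",
                                               "mCherry_CNO",
                                               "mCherry_saline")) {
  rows <- lapply(arms, function(arm) {
    do.call(rbind, lapply(seq_len(n_subjects), function(i) {
      preference_ratio(generate_preference_trial(
        sim, arm, sprintf("%s_s%02d", arm, i)))
    }))
  })
  trials <- do.call(rbind, rows)
  vir <- sub("_.*$", "", trials$arm)
  drug <- sub("^.*_", "", trials$arm)
  tab <- data.frame(value = trials$side_by_side_partner_s,
                    group = vir, treatment = drug)
  cno <- trials[drug == "CNO", ]
  list(trials = trials,
       anova_sbs = two_way_anova(tab),
       kruskal_cno = kruskal_wallis(list(
         partner = cno$side_by_side_partner_s,
         stranger = cno$side_by_side_stranger_s)))
}

#' Patch-clamp experiment: spontaneous, evoked, steps, bath protocols
#'
#' Generates `n_cells` cells per group for each requested protocol and
#' produces the per-cell summaries and the group statistics used in
#' synaptic-transmission comparisons: unpaired t tests on spontaneous PSC
#' frequency/amplitude and on normalized E/I ratios, F-I curves with
#' rheobase, and the mixed ANOVA on the bath-drug paired frequencies.
#'
#' @param sim A [sim_config()].
#' @param n_cells Cells per group.
#' @param groups Two group labels (second is the control for E/I
#'   normalization).
#' @param protocols Subset of `spontaneous_vclamp`, `evoked_vclamp`,
#'   `current_steps`, `bath_da`.
#' @return List with per-protocol cell tables and [stat_result()]s.
#' @export
run_ephys_experiment <- function(sim, n_cells = 8,
                                 groups = c("cohabitation", "control"),
                                 protocols = c("spontaneous_vclamp",
                                               "evoked_vclamp",
                                               "current_steps", "bath_da")) {
  out <- list()
  cells <- function(g) sprintf("%s_c%02d", g, seq_len(n_cells))
  if ("spontaneous_vclamp" %in% protocols) {
    tab <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(cells(g), function(cid) {
        ss <- generate_sweep_set(sim, "spontaneous_vclamp", g, cid)
        sw <- ss$sweeps[[1]]
        ev <- detect_events(sw, fs = ss$fs, polarity = "inward")
        cbind(data.frame(cell_id = cid, group = g),
              event_stats(ev, sw$duration_s))
      }))
    }))
    out$spontaneous <- tab
    out$t_freq <- unpaired_t(tab$frequency_hz[tab$group == groups[1]],
                             tab$frequency_hz[tab$group == groups[2]])
    out$t_amp <- unpaired_t(tab$mean_amplitude_pA[tab$group == groups[1]],
                            tab$mean_amplitude_pA[tab$group == groups[2]])
  }
  if ("evoked_vclamp" %in% protocols) {
    ei <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(cells(g), function(cid) {
        ei_ratio_from_sweep_set(
          generate_sweep_set(sim, "evoked_vclamp", g, cid),
          n_required = sim$evoked_n_trials)
      }))
    }))
    ei <- normalize_ei(ei, control_group = groups[2])
    out$ei <- ei
    out$t_ei <- unpaired_t(ei$normalized_ratio[ei$group == groups[1]],
                           ei$normalized_ratio[ei$group == groups[2]])
  }
  if ("current_steps" %in% protocols) {
    fi <- lapply(groups, function(g) {
      lapply(cells(g), function(cid) {
        fi_curve(generate_sweep_set(sim, "current_steps", g, cid))
      })
    })
    names(fi) <- groups
    out$fi <- fi
    long <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(seq_along(fi[[g]]), function(i) {
        f <- fi[[g]][[i]]
        data.frame(subject = sprintf("%s_c%02d", g, i), group = g,
                   condition = sprintf("I%03d", f$step_currents_pA),
                   value = f$spike_counts)
      }))
    }))
    out$anova_fi <- mixed_anova(long, posthoc = FALSE)
  }
  if ("bath_da" %in% protocols) {
    bath <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(cells(g), function(cid) {
        bath_da_compare(generate_sweep_set(sim, "bath_da", g, cid))
      }))
    }))
    out$bath <- bath
    long <- rbind(
      data.frame(subject = bath$cell_id, group = bath$group,
                 condition = "baseline", value = bath$baseline_frequency_hz),
      data.frame(subject = bath$cell_id, group = bath$group,
                 condition = "da", value = bath$da_frequency_hz))
    out$anova_bath <- mixed_anova(long)
  }
  out
}

#' Run a full experiment from a run configuration
#'
#' Synthetic mode generates data, runs every analysis stage, and collects
#' the statistics; source-data mode loads long-format summary tables and
#' dispatches each recipe's test (no random stream is touched). When
#' `out_dir` is set, summary and stats CSVs are written there; every output
#' carries a hash of the configuration.
#'
#' @param config A [run_config()].
#' @return List with `stats` (named [stat_result()]s), `tables` (the
#'   analysis data frames), `stats_table` (flat reporting table),
#'   `config_hash`, and `log` (stage-boundary counts).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  hash <- sprintf("%08x", derive_seed(0L, paste(
    deparse(config[setdiff(names(config), "out_dir")]), collapse = "")))
  log <- character(0)
  results <- list()
  tables <- list()

  if (config$mode == "synthetic") {
    sim <- config$sim
    ph <- run_photometry_experiment(sim, config$n_animals)
    results$photometry_rm_anova <- ph$anova
    tables$photometry <- ph$summaries
    log <- c(log, sprintf("photometry: %d sessions, %d bouts excluded",
                          nrow(ph$summaries), ph$n_bouts_excluded))

    ep <- run_ephys_experiment(sim, config$n_cells)
    results$sepsc_frequency_t <- ep$t_freq
    results$sepsc_amplitude_t <- ep$t_amp
    results$ei_ratio_t <- ep$t_ei
    results$fi_mixed_anova <- ep$anova_fi
    results$bath_mixed_anova <- ep$anova_bath
    tables$spontaneous <- ep$spontaneous
    tables$ei <- ep$ei
    tables$bath <- ep$bath
    log <- c(log, sprintf("ephys: %d cells per group x 4 protocols",
                          config$n_cells))

    pr <- run_preference_experiment(sim, config$n_subjects)
    results$preference_two_way_anova <- pr$anova_sbs
    results$preference_kruskal <- pr$kruskal_cno
    tables$preference <- pr$trials
    log <- c(log, sprintf("behavior: %d trials", nrow(pr$trials)))
  } else {
    for (rc in config$recipes) {
      tab <- utils::read.csv(rc$path, stringsAsFactors = FALSE)
      need <- unlist(rc[intersect(names(rc),
        c("value", "within", "between", "subject", "f1", "f2"))])
      miss <- setdiff(need, names(tab))
      if (length(miss)) {
        stop("recipe '", rc$name, "': table lacks column(s) ",
             paste(miss, collapse = ", "))
      }
      args <- rc[setdiff(names(rc), c("name", "path", "test"))]
      results[[rc$name]] <- switch(rc$test,
        paired_t = paired_t(tab[[rc$x]], tab[[rc$y]]),
        unpaired_t = unpaired_t(tab[[rc$x]], tab[[rc$y]]),
        rm_anova_gg = do.call(rm_anova_gg, c(list(tab),
          args[setdiff(names(args), c("x", "y"))])),
        mixed_anova = do.call(mixed_anova, c(list(tab),
          args[setdiff(names(args), c("x", "y"))])),
        two_way_anova = do.call(two_way_anova, c(list(tab),
          args[setdiff(names(args), c("x", "y"))])),
        kruskal_wallis = kruskal_wallis(
          split(tab[[rc$value]], tab[[rc$group %||% "group"]])),
        stop("recipe '", rc$name, "': unknown test '", rc$test, "'"))
      tables[[rc$name]] <- tab
      log <- c(log, sprintf("recipe %s: %d rows", rc$name, nrow(tab)))
    }
  }

  flat <- stats_table(results)
  flat$config_hash <- hash
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(flat, file.path(config$out_dir, "stats.csv"),
                     row.names = FALSE)
    for (nm in names(tables)) {
      utils::write.csv(tables[[nm]],
                       file.path(config$out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
    }
    writeLines(c(paste("config_hash:", hash), log),
               file.path(config$out_dir, "run.log"))
  }
  list(stats = results, tables = tables, stats_table = flat,
       config_hash = hash, log = log)
}
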