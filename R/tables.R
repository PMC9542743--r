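# Flat-table views of simulation runs, the CSV/JSON artifact writers, and
# the independent table-based analysis path used by `evaluate`.
#
# Schemas (UTF-8, comma-delimited, header row; generation is 0-based with
# generation 0 = the first, asocial/guessing generation):
#   decisions.csv: network, condition, trial, generation, agent, feature,
#                  decision, companion_agent (NA for generation 0),
#                  resampled_count
#   evidence.csv:  network, condition, trial, generation, feature,
#                  test_index, outcome
#   trajectory.csv: the per feature-generation trajectory (see run_trial)

DECISIONS_COLUMNS <- c("network", "condition", "trial", "generation",
                       "agent", "feature", "decision", "companion_agent",
                       "resampled_count")
EVIDENCE_COLUMNS <- c("network", "condition", "trial", "generation",
                      "feature", "test_index", "outcome")

#' Decisions table of one or more runs
#'
#' @param runs a `network_run` or list of them.
#' @return data frame, one row per agent-feature-generation-trial-network.
#' @export
as_decisions_table <- function(runs) {
  if (inherits(runs, "network_run")) runs <- list(runs)
  parts <- lapply(runs, function(run) {
    cfg <- run$config
    n <- cfg$N
    f <- cfg$F_feat
    do.call(rbind, lapply(seq_along(run$trials), function(tr) {
      gens <- run$trials[[tr]]$generations
      do.call(rbind, lapply(seq_along(gens) - 1L, function(g) {
        gen <- gens[[g + 1L]]
        data.frame(
          network = run$network_id, condition = cfg$condition, trial = tr,
          generation = g,
          agent = rep(seq_len(n), f),
          feature = rep(seq_len(f), each = n),
          decision = as.integer(gen$decisions),
          companion_agent = rep(gen$companions, f),
          resampled_count = as.integer(gen$resamples)
        )
      }))
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Evidence table of one or more runs
#'
#' @inheritParams as_decisions_table
#' @return data frame, one row per outcome y_ijt.
#' @export
as_evidence_table <- function(runs) {
  if (inherits(runs, "network_run")) runs <- list(runs)
  parts <- lapply(runs, function(run) {
    cfg <- run$config
    f <- cfg$F_feat
    J <- cfg$J
    if (J == 0) return(NULL)
    do.call(rbind, lapply(seq_along(run$trials), function(tr) {
      blocks <- run$trials[[tr]]$blocks
      do.call(rbind, lapply(blocks, function(b) {
        data.frame(
          network = run$network_id, condition = cfg$condition, trial = tr,
          generation = b$generation,
          feature = rep(seq_len(f), J),
          test_index = rep(seq_len(J), each = f),
          outcome = as.integer(b$outcomes)
        )
      }))
    }))
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Trajectory table of one or more runs
#'
#' @inheritParams as_decisions_table
#' @return data frame, one row per feature-generation-trial-network.
#' @export
as_trajectory_table <- function(runs) {
  if (inherits(runs, "network_run")) runs <- list(runs)
  out <- do.call(rbind, lapply(runs, `[[`, "trajectory"))
  rownames(out) <- NULL
  out
}

config_as_list <- function(cfg) {
  cfg$init_decisions <- NULL
  unclass(cfg)
}

#' Write the CSV/JSON artifacts of a simulation
#'
#' Writes `decisions.csv`, `evidence.csv`, `trajectory.csv`, `config.json`
#' (one entry per condition) and `manifest.json` (root seeds, package
#' version, per-file md5 checksums).
#'
#' @inheritParams as_decisions_table
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(runs, dir) {
  if (inherits(runs, "network_run")) runs <- list(runs)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(as_decisions_table(runs), file.path(dir, "decisions.csv"),
            row.names = FALSE)
  write.csv(as_evidence_table(runs), file.path(dir, "evidence.csv"),
            row.names = FALSE)
  write.csv(as_trajectory_table(runs), file.path(dir, "trajectory.csv"),
            row.names = FALSE)

  cfgs <- list()
  for (run in runs) {
    key <- if (is.na(run$config$condition)) "custom" else run$config$condition
    cfgs[[key]] <- config_as_list(run$config)
  }
  jsonlite::write_json(cfgs, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- c("decisions.csv", "evidence.csv", "trajectory.csv", "config.json")
  manifest <- list(
    package = "socialsampler",
    version = as.character(packageVersion("socialsampler")),
    seeds = unlist(lapply(cfgs, `[[`, "seed")),
    checksums = as.list(setNames(tools::md5sum(file.path(dir, files)), files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

check_schema <- function(df, columns, what) {
  for (col in columns) {
    if (!col %in% names(df)) {
      ss_error("schema_error",
               sprintf("%s table is missing column '%s'", what, col))
    }
  }
  if (nrow(df) == 0) {
    ss_error("schema_error", sprintf("%s table has no rows", what))
  }
  invisible(TRUE)
}

#' Rebuild analysis rows from flat tables
#'
#' Independent of the in-memory `network_run` objects: recomputes popularity,
#' evidence fractions and the ideal posterior from a decisions table, an
#' evidence table, and per-condition configuration entries (as written to
#' `config.json`). Only social generations (generation >= 1) are returned.
#'
#' @param decisions decisions table (see [as_decisions_table()]).
#' @param evidence evidence table (see [as_evidence_table()]).
#' @param configs named list of per-condition settings; each entry needs
#'   `theta1`, `theta0`, `J`, `evidence_lag` and `censored`.
#' @return data frame of analysis rows.
#' @export
rows_from_tables <- function(decisions, evidence, configs) {
  check_schema(decisions, setdiff(DECISIONS_COLUMNS, "companion_agent"),
               "decisions")
  check_schema(evidence, EVIDENCE_COLUMNS, "evidence")
  ss_check(is_binary(decisions$decision), "schema_error",
           "column 'decision' must be 0/1")
  ss_check(is_binary(evidence$outcome), "schema_error",
           "column 'outcome' must be 0/1")

  key <- function(net, cond, tr, gen, feat) {
    paste(net, cond, tr, gen, feat, sep = "\r")
  }
  cfg_for <- function(cond) {
    k <- if (is.na(cond)) "custom" else as.character(cond)
    cfg <- configs[[k]] %||% configs[[1]]
    ss_check(!is.null(cfg), "schema_error",
             sprintf("no configuration entry for condition '%s'", k))
    cfg
  }

  pop <- tapply(decisions$decision,
                key(decisions$network, decisions$condition, decisions$trial,
                    decisions$generation, decisions$feature),
                mean)

  blk <- stats::aggregate(
    outcome ~ network + condition + trial + generation + feature,
    data = evidence, FUN = sum)
  blk <- blk[order(blk$network, blk$condition, blk$trial, blk$feature,
                   blk$generation), , drop = FALSE]
  blk$S_cum <- stats::ave(blk$outcome,
                          paste(blk$network, blk$condition, blk$trial,
                                blk$feature, sep = "\r"),
                          FUN = cumsum)
  bkey <- key(blk$network, blk$condition, blk$trial, blk$generation,
              blk$feature)

  grid <- unique(decisions[decisions$generation >= 1,
                           c("network", "condition", "trial", "generation",
                             "feature")])
  grid <- grid[order(grid$network, grid$condition, grid$trial,
                     grid$generation, grid$feature), , drop = FALSE]

  cond_chr <- as.character(grid$condition)
  lag <- vapply(cond_chr, function(cd) as.integer(cfg_for(cd)$evidence_lag),
                integer(1))
  J <- vapply(cond_chr, function(cd) as.integer(cfg_for(cd)$J), integer(1))
  th1 <- vapply(cond_chr, function(cd) as.numeric(cfg_for(cd)$theta1),
                numeric(1))
  th0 <- vapply(cond_chr, function(cd) as.numeric(cfg_for(cd)$theta0),
                numeric(1))
  cens <- vapply(cond_chr, function(cd) isTRUE(cfg_for(cd)$censored),
                 logical(1))

  gblock <- grid$generation - lag
  bidx <- match(key(grid$network, grid$condition, grid$trial, gblock,
                    grid$feature), bkey)
  S_last <- blk$outcome[bidx]
  S_cum <- blk$S_cum[bidx]
  t_eff <- gblock + 1L
  n_obs <- t_eff * J

  rows <- data.frame(
    network = grid$network, condition = grid$condition, trial = grid$trial,
    generation = grid$generation, feature = grid$feature,
    popularity = as.numeric(pop[key(grid$network, grid$condition, grid$trial,
                                    grid$generation, grid$feature)]),
    p_prev = as.numeric(pop[key(grid$network, grid$condition, grid$trial,
                                grid$generation - 1L, grid$feature)]),
    S_last = S_last, J = J, S_cum = S_cum, n_obs = n_obs,
    theta1 = th1, theta0 = th0, censored = cens
  )
  rows$total_evidence_fraction <-
    ifelse(rows$n_obs > 0, rows$S_cum / rows$n_obs, NA_real_)
  rows$last_evidence_fraction <-
    ifelse(rows$J > 0 & !is.na(rows$S_last), rows$S_last / rows$J, NA_real_)
  rows$ideal_posterior <- ideal_posterior(
    rows$S_cum, t = t_eff, J = rows$J, theta1 = rows$theta1,
    theta0 = rows$theta0)
  rownames(rows) <- NULL
  rows
}
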