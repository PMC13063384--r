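# CSV/JSON readers and writers, report rendering, pipeline runner.
# CSV dialect throughout: UTF-8, comma-separated, dot decimal, header
# row mandatory.

.read_csv <- function(path) {
  if (!file.exists(path)) stop_schema(paste("file not found:", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE,
                                 stringsAsFactors = FALSE),
                 error = function(e) stop_schema(paste("cannot parse", path,
                                                       ":", conditionMessage(e))))
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop_schema(paste("empty table:", path))
  }
  df
}

.require_columns <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_schema(sprintf("%s: missing column(s) %s", path,
                        paste(miss, collapse = ", ")))
  }
}

#' Read a Delphi ratings CSV
#'
#' Expects a header row of item codes and one data row per expert; an
#' optional leading `expert` column carries expert identifiers.  Rows
#' that are entirely empty (a non-responding expert) are dropped whole;
#' partially missing rows are a schema error.
#'
#' @param path CSV file path.
#' @param round_id consultation round recorded on the result.
#' @return a [rating_matrix()].
#' @export
read_ratings_csv <- function(path, round_id = 1L) {
  df <- .read_csv(path)
  if (tolower(names(df)[1]) %in% c("expert", "expert_id", "id")) {
    rownames(df) <- df[[1]]
    df <- df[, -1, drop = FALSE]
  }
  m <- as.matrix(df)
  storage.mode(m) <- "numeric"
  all_na <- rowSums(!is.na(m)) == 0L
  m <- m[!all_na, , drop = FALSE]
  part <- which(rowSums(is.na(m)) > 0L)
  if (length(part)) {
    stop_schema(sprintf("%s: row %d has missing cells; drop non-responders as whole rows",
                        path, part[1]))
  }
  rating_matrix(m, round_id = round_id)
}

#' Read an expert authority CSV
#'
#' Expects columns `expert`, `practical_experience`,
#' `theoretical_analysis`, `literature`, `intuition` (levels high /
#' medium / low) and `familiarity`.  Computes Ca, Cs and Cr per expert.
#'
#' @param path CSV file path.
#' @return a `data.frame` with the raw levels plus `ca`, `cs`, `cr`.
#' @export
read_authority_csv <- function(path) {
  df <- .read_csv(path)
  need <- c("expert", "practical_experience", "theoretical_analysis",
            "literature", "intuition", "familiarity")
  .require_columns(df, need, path)
  df$ca <- vapply(seq_len(nrow(df)), function(i) {
    judgment_basis(c(practical_experience = df$practical_experience[i],
                     theoretical_analysis = df$theoretical_analysis[i],
                     literature = df$literature[i],
                     intuition = df$intuition[i]))
  }, numeric(1))
  df$cs <- familiarity_score(df$familiarity)
  df$cr <- authority_coefficient(df$ca, df$cs)
  df
}

#' Read a DMU panel CSV
#'
#' One row per DMU.  Input and output columns are identified either by
#' `input_` / `output_` name prefixes or through a sidecar roles JSON
#' (an object mapping column name to `"input"` or `"output"`).  An
#' optional `dmu` column carries unit identifiers.  Non-numeric or
#' nonpositive cells are schema errors naming the offending cell.
#'
#' @param path CSV file path.
#' @param roles optional path to a roles JSON or a named character
#'   vector.
#' @return a [dmu_panel()].
#' @export
read_panel_csv <- function(path, roles = NULL) {
  df <- .read_csv(path)
  ids <- NULL
  if (tolower(names(df)[1]) %in% c("dmu", "id", "institution")) {
    ids <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  if (is.null(roles)) {
    role <- ifelse(startsWith(names(df), "input_"), "input",
                   ifelse(startsWith(names(df), "output_"), "output", NA))
    if (anyNA(role)) {
      stop_schema(sprintf("%s: column '%s' has no role; use input_/output_ prefixes or a roles file",
                          path, names(df)[which(is.na(role))[1]]))
    }
    names(role) <- names(df)
  } else {
    if (is.character(roles) && length(roles) == 1L && file.exists(roles)) {
      roles <- unlist(jsonlite::read_json(roles, simplifyVector = TRUE))
    }
    miss <- setdiff(names(df), names(roles))
    if (length(miss)) {
      stop_schema(sprintf("%s: no role for column(s) %s", path,
                          paste(miss, collapse = ", ")))
    }
    role <- unlist(roles)[names(df)]
  }
  for (cn in names(df)) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      stop_schema(sprintf("%s: non-numeric value at row %d, column '%s'",
                          path, which(is.na(v))[1], cn))
    }
    if (any(v <= 0)) {
      stop_schema(sprintf("%s: nonpositive value at row %d, column '%s' (DEA requires positive data)",
                          path, which(v <= 0)[1], cn))
    }
    df[[cn]] <- v
  }
  X <- as.matrix(df[, role == "input", drop = FALSE])
  Y <- as.matrix(df[, role == "output", drop = FALSE])
  if (ncol(X) == 0L || ncol(Y) == 0L) {
    stop_schema(paste(path, ": need at least one input and one output column"))
  }
  dmu_panel(X, Y, ids = ids)
}

#' Read an indicator metadata/statistics CSV
#'
#' Reads a table of hierarchical indicators with their
#' structure-process-outcome tags and consultation statistics: columns
#' `id`, `label`, `spo`, and optionally `mean`, `sd`, `cv`,
#' `full_score_rate` (in percent).  Hierarchy levels are derived from
#' the code depth; the full-score rate is converted to a proportion.
#'
#' @param path CSV file path.
#' @return a `data.frame` with `id`, `label`, `level`, `spo` and any
#'   statistic columns present (`full_score_rate` as a proportion).
#' @export
read_indicator_csv <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("id", "label", "spo"), path)
  meta <- item_meta(df$id, df$label, df$spo)
  for (cn in intersect(c("mean", "sd", "cv", "full_score_rate"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      stop_schema(sprintf("%s: non-numeric value at row %d, column '%s'",
                          path, which(is.na(v))[1], cn))
    }
    meta[[cn]] <- if (cn == "full_score_rate") v / 100 else v
  }
  meta
}

#' Read a per-DMU efficiency table CSV
#'
#' Reads an already computed efficiency table (columns `dmu`, `oe`,
#' `te`, and optionally `se`, `rts`, `s_minus`, `s_plus`, `efficiency`),
#' e.g. a published results table used as a worked example.
#'
#' @param path CSV file path.
#' @return a validated `data.frame`.
#' @export
read_efficiency_csv <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("dmu", "oe", "te"), path)
  for (cn in intersect(c("oe", "te", "se", "s_minus", "s_plus"), names(df))) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (anyNA(v)) {
      stop_schema(sprintf("%s: non-numeric value at row %d, column '%s'",
                          path, which(is.na(v))[1], cn))
    }
    df[[cn]] <- v
  }
  if (any(df$oe <= 0 | df$oe > 1) || any(df$te <= 0 | df$te > 1)) {
    stop_schema(paste(path, ": efficiency scores must lie in (0, 1]"))
  }
  df
}

#' Write a concordance result as JSON
#'
#' @param w a `kendall_w` object.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_concordance_json <- function(w, path) {
  stopifnot(inherits(w, "kendall_w"))
  jsonlite::write_json(list(w = w$w, chi2 = w$chi2, df = w$df,
                            p_value = w$p_value,
                            tie_corrected = w$tie_corrected),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render DEA reports
#'
#' Writes the standard reporting artifacts of a DEA run into a
#' directory: `efficiency.csv` (per-DMU OE/TE/SE, returns-to-scale,
#' total slacks and efficiency label, with an appended `Average` row),
#' `slacks.csv` (per-indicator input/output slacks of the inefficient
#' DMUs), and `summary.txt` (counts and, for each inefficient DMU, its
#' efficient peer set from the positive CCR intensity weights).
#'
#' @param d a `dea` object fitted with `model = "both"`.
#' @param dir output directory (created if needed).
#' @param digits reported decimals (default 3).
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(d, dir, digits = 3) {
  stopifnot(inherits(d, "dea"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- dea_efficiency_table(d, digits = digits)
  avg <- data.frame(dmu = "Average",
                    oe = round_half_up(mean(d$scores$oe), digits),
                    te = round_half_up(mean(d$scores$te), digits),
                    se = round_half_up(mean(d$scores$se), digits),
                    rts = "", s_minus = NA_real_, s_plus = NA_real_,
                    efficiency = "", stringsAsFactors = FALSE)
  f1 <- file.path(dir, "efficiency.csv")
  utils::write.csv(rbind(tab, avg), f1, row.names = FALSE, na = "")

  ineff <- which(d$scores$classification != "efficient")
  sl <- cbind(
    data.frame(dmu = d$scores$dmu[ineff], stringsAsFactors = FALSE),
    round_half_up(d$ccr$slack_input[ineff, , drop = FALSE], digits),
    round_half_up(d$ccr$slack_output[ineff, , drop = FALSE], digits))
  names(sl) <- c("dmu",
                 paste0("s_minus_", colnames(d$panel$X)),
                 paste0("s_plus_", colnames(d$panel$Y)))
  f2 <- file.path(dir, "slacks.csv")
  utils::write.csv(sl, f2, row.names = FALSE)

  f3 <- file.path(dir, "summary.txt")
  s <- summarize_dea(d, digits = digits)
  lines <- c(
    sprintf("DMUs evaluated: %d", s$n_dmu),
    sprintf("Efficient: %d; inefficient: %d", s$n_efficient, s$n_inefficient),
    sprintf("Mean OE = %.3f, TE = %.3f, SE = %.3f",
            s$means["oe"], s$means["te"], s$means["se"]),
    "")
  for (j in ineff) {
    peers <- d$scores$dmu[d$ccr$lambda[j, ] > d$tol]
    lines <- c(lines, sprintf("DMU %s (OE = %.3f): efficient peers %s",
                              d$scores$dmu[j],
                              round_half_up(d$scores$oe[j], digits),
                              paste(peers, collapse = ", ")))
  }
  writeLines(lines, f3)
  invisible(c(f1, f2, f3))
}

#' Assemble and validate a pipeline configuration
#'
#' @param ratings path to a Delphi ratings CSV (optional stage).
#' @param panel path to a DMU panel CSV (optional stage).
#' @param roles optional roles JSON path for the panel.
#' @param thresholds a [screening_thresholds()] object.
#' @param tie_correction logical, for the concordance statistic.
#' @param cap,r_min indicator-selection cap and correlation threshold
#'   (selection runs only when the panel carries more candidates than
#'   the cap).
#' @param model,tol,projection_mode DEA options.
#' @param seed integer seed recorded with the run.
#' @param out output directory.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(ratings = NULL, panel = NULL, roles = NULL,
                            thresholds = screening_thresholds(),
                            tie_correction = TRUE,
                            cap = NULL, r_min = 0.7,
                            model = "both", tol = 1e-6,
                            projection_mode = "standard",
                            seed = 1L, out = tempfile("nhrdea-run-")) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  if (!model %in% c("both", "ccr", "bcc")) stop_invalid("unknown DEA model")
  if (!projection_mode %in% c("standard", "slack_only")) {
    stop_invalid("unknown projection mode")
  }
  structure(list(ratings = ratings, panel = panel, roles = roles,
                 thresholds = thresholds, tie_correction = tie_correction,
                 cap = cap, r_min = r_min, model = model, tol = tol,
                 projection_mode = projection_mode,
                 seed = as.integer(seed), out = out),
            class = "pipeline_config")
}

#' Run the analysis pipeline
#'
#' Chains the consultation-statistics, indicator-screening and DEA
#' stages on file inputs; stages without an input are skipped.  Every
#' run writes its resolved configuration and a manifest listing each
#' artifact with its MD5 hash, so a rerun with an identical
#' configuration is byte-identical.  A panel whose dimensions violate
#' the DEA rules of thumb aborts before solving.
#'
#' @param config a [pipeline_config()].
#' @return the manifest (a `data.frame` of `file`, `md5`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      nhr_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "nhrdea_stage_error")
    })
  }
  cfg_path <- file.path(config$out, "config.json")
  jsonlite::write_json(
    list(thresholds = unclass(config$thresholds),
         tie_correction = config$tie_correction, cap = config$cap,
         r_min = config$r_min, model = config$model, tol = config$tol,
         projection_mode = config$projection_mode, seed = config$seed),
    cfg_path, auto_unbox = TRUE, null = "null", digits = NA)
  files <- c(files, cfg_path)

  if (!is.null(config$ratings)) {
    stage("delphi-stats", {
      rm_ <- read_ratings_csv(config$ratings)
      st <- delphi_item_stats(rm_)
      scr <- screen_delphi_items(st, config$thresholds)
      out_stats <- scr
      out_stats$full_score_rate <- round_half_up(100 * out_stats$full_score_rate, 1)
      f <- file.path(config$out, "item_stats.csv")
      utils::write.csv(out_stats, f, row.names = FALSE)
      files <- c(files, f)
      w <- kendalls_w(rm_, tie_correction = config$tie_correction)
      fw <- file.path(config$out, "concordance.json")
      write_concordance_json(w, fw)
      files <- c(files, fw)
    })
  }

  if (!is.null(config$panel)) {
    stage("dea-run", {
      panel <- read_panel_csv(config$panel, roles = config$roles)
      if (!panel$rule_of_thumb$feasible) {
        stop_invalid("panel dimensions violate the DEA rules of thumb; aborting before solving")
      }
      d <- dea(panel, model = "both", tol = config$tol)
      files <- c(files, render_report(d, config$out))
    })
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  fm <- file.path(config$out, "manifest.csv")
  utils::write.csv(manifest, fm, row.names = FALSE)
  invisible(manifest)
}
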