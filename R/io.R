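## Trajectory and expression-table IO, run configuration, scenario driver.
## File dialect: UTF-8, tab-separated, "." decimal, "inf" for infinite
## lifetimes, leading "# key=value" comment lines carrying config hash, seed
## and software version.

count_comment_lines <- function(path) {
  n <- 0L
  con <- file(path, "r", encoding = "UTF-8")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !startsWith(line, "#")) break
    n <- n + 1L
  }
  n
}

read_meta <- function(path) {
  lines <- readLines(path, n = 50L, encoding = "UTF-8")
  lines <- lines[startsWith(lines, "#")]
  kv <- strsplit(sub("^#\\s*", "", lines), "=", fixed = TRUE)
  kv <- kv[lengths(kv) == 2]
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}

#' Write a trajectory to TSV
#'
#' Long format (`format = "long"`): columns `t_min`, `series` (one of
#' `mRNA`, `protein`, `volume`, `mass`, `free_fraction_rnap`,
#' `free_fraction_ribo`), `gene_id` (empty for cell-level series), `value`.
#' The compact wide format keeps only the cell-level series, one column
#' each. Uses data.table for streamable writes at 2000 genes.
#'
#' @param traj `volscale_trajectory`.
#' @param path output TSV.
#' @param format `"long"` or `"wide"`.
#' @param meta named list of `# key=value` header entries.
#' @export
write_trajectory <- function(traj, path, format = c("long", "wide"),
                             meta = list()) {
  format <- match.arg(format)
  meta <- utils::modifyList(list(version = pkg_version()), meta)
  Tn <- length(traj$time)
  G <- ncol(traj$m)
  if (format == "long") {
    ids <- colnames(traj$m)
    dt <- data.table::data.table(
      t_min = c(rep(traj$time, times = 2 * G), rep(traj$time, times = 4)),
      series = c(rep("mRNA", Tn * G), rep("protein", Tn * G),
                 rep(c("volume", "mass", "free_fraction_rnap",
                       "free_fraction_ribo"), each = Tn)),
      gene_id = c(rep(ids, each = Tn), rep(ids, each = Tn),
                  rep("", 4 * Tn)),
      value = c(as.vector(traj$m), as.vector(traj$p),
                traj$V, traj$M, traj$F_n, traj$F_r))
  } else {
    dt <- data.table::data.table(
      t_min = traj$time, volume = traj$V, mass = traj$M,
      n_rnap = traj$n, n_ribosome = traj$r,
      free_fraction_rnap = traj$F_n, free_fraction_ribo = traj$F_r)
  }
  con <- file(path, "w", encoding = "UTF-8")
  writeLines(meta_header(meta), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read a long-format trajectory TSV
#'
#' Returns a light trajectory (no genome attached): time grid, `m`/`p`
#' matrices and the cell-level series.
#'
#' @param path TSV written by [write_trajectory()] (long format).
#' @return list with `time`, `m`, `p`, `V`, `M`, `F_n`, `F_r`, `meta`.
#' @export
read_trajectory <- function(path) {
  skip <- count_comment_lines(path)
  dt <- data.table::fread(path, sep = "\t", skip = skip, header = TRUE,
                          colClasses = list(character = c("series", "gene_id")))
  need <- c("t_min", "series", "gene_id", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("trajectory file missing column(s): ", paste(miss, collapse = ", "))
  time <- sort(unique(dt$t_min))
  wide <- function(ser) {
    sub <- dt[dt$series == ser, ]
    ids <- unique(sub$gene_id)
    mat <- matrix(sub$value, nrow = length(time), ncol = length(ids),
                  dimnames = list(NULL, ids))
    mat
  }
  cellv <- function(ser) dt$value[dt$series == ser]
  list(time = time, m = wide("mRNA"), p = wide("protein"),
       V = cellv("volume"), M = cellv("mass"),
       F_n = cellv("free_fraction_rnap"), F_r = cellv("free_fraction_ribo"),
       meta = read_meta(path))
}

#' Write an expression-versus-volume table
#'
#' Emits the three-file layout consumed by [read_expression_table()]:
#' `expression` (header `gene_id  volume_1 ... volume_B`), `volumes`
#' (columns `bin`, `volume`) and optionally `lifetimes` (columns `gene_id`,
#' `tau_m`).
#'
#' @param tab list with `expression` (genes x bins matrix, rownames = gene
#'   ids), `volumes`, optional `lifetimes` (named).
#' @param expression,volumes,lifetimes output paths (`lifetimes` optional).
#' @param meta named header entries.
#' @export
write_expression_table <- function(tab, expression, volumes, lifetimes = NULL,
                                   meta = list()) {
  B <- length(tab$volumes)
  stopifnot(ncol(tab$expression) == B)
  con <- file(expression, "w", encoding = "UTF-8")
  writeLines(meta_header(meta), con)
  writeLines(paste(c("gene_id", paste0("volume_", seq_len(B))), collapse = "\t"), con)
  rows <- apply(tab$expression, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(paste(rownames(tab$expression), rows, sep = "\t"), con)
  close(con)
  con <- file(volumes, "w", encoding = "UTF-8")
  writeLines(c(meta_header(meta), "bin\tvolume",
               paste(seq_len(B), fmt_num(tab$volumes), sep = "\t")), con)
  close(con)
  if (!is.null(lifetimes) && !is.null(tab$lifetimes)) {
    lt <- tab$lifetimes[rownames(tab$expression)]
    con <- file(lifetimes, "w", encoding = "UTF-8")
    writeLines(c(meta_header(meta), "gene_id\ttau_m",
                 paste(rownames(tab$expression), fmt_num(lt), sep = "\t")), con)
    close(con)
  }
  invisible(expression)
}

#' Read an expression-versus-volume table
#'
#' @param expression path to the gene x volume-bin TSV.
#' @param volumes path to the companion bin -> volume TSV.
#' @param lifetimes optional path to the gene -> tau_m TSV.
#' @return list with `expression` matrix, `volumes`, `lifetimes` (or NULL).
#' @export
read_expression_table <- function(expression, volumes, lifetimes = NULL) {
  readtsv <- function(path) {
    skip <- count_comment_lines(path)
    utils::read.delim(path, skip = skip, header = TRUE, sep = "\t",
                      check.names = FALSE, stringsAsFactors = FALSE)
  }
  ex <- readtsv(expression)
  if (names(ex)[1] != "gene_id") stop("expression table must start with gene_id")
  mat <- as.matrix(ex[, -1, drop = FALSE])
  rownames(mat) <- ex$gene_id
  vol <- readtsv(volumes)
  if (!all(c("bin", "volume") %in% names(vol)))
    stop("volumes table needs columns bin, volume")
  v <- vol$volume[order(vol$bin)]
  if (ncol(mat) != length(v)) stop("bin count mismatch between files")
  if (length(v) < 3) stop("need at least 3 volume bins")
  if (any(diff(v) <= 0)) stop("volumes must be strictly increasing")
  if (any(mat < 0)) stop("negative expression values")
  lt <- NULL
  if (!is.null(lifetimes)) {
    lf <- readtsv(lifetimes)
    if (!all(c("gene_id", "tau_m") %in% names(lf)))
      stop("lifetimes table needs columns gene_id, tau_m")
    lt <- stats::setNames(lf$tau_m, lf$gene_id)[rownames(mat)]
  }
  list(expression = mat, volumes = v, lifetimes = lt)
}

## Run configuration -----------------------------------------------------------

default_config <- function() {
  list(
    seed = 1L,
    globals = list(),
    genome = list(n_genes = 2000, K_mean = 6e3, K_cv = 0.5,
                  lifetime_mean = 10, lifetime_cv = 1, gamma_cv = 0,
                  n_degradable = 0, tau_p_deg = 10),
    experiment = list(scenario = "lognormal_ensemble", burn_in = 20,
                      t_end = 800, stop_multiplier = 9, dt_out = 1,
                      special_multipliers = c(20, 0.2),
                      ratio_threshold = NULL, n_cycles = 8),
    fit = list(n_bins = 40, weights = "none")
  )
}

#' Read and validate a JSON run configuration
#'
#' Blocks: `globals` (arguments of [global_params()]), `genome` (either
#' `path` to a gene TSV or [make_genome()] generator arguments), `experiment`
#' (`scenario` in homogeneous / two_special / lognormal_ensemble /
#' cell_cycle, burn-in, t_end, stop multiplier, output cadence, cell-cycle
#' options), `fit` (bins, weights), and a top-level `seed`. Unknown keys are
#' rejected; the config hash is embedded in every output file.
#'
#' @param path JSON file.
#' @return validated config list with defaults filled and `hash` attached.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg a config list (as from JSON).
#' @export
validate_run_config <- function(cfg) {
  def <- default_config()
  cfg$hash <- NULL   # revalidating an already-validated config is fine
  bad <- setdiff(names(cfg), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  allowed_blocks <- list(
    globals = names(formals(global_params)),
    genome = c("path", names(formals(make_genome))),
    experiment = names(def$experiment),
    fit = names(def$fit))
  for (blk in names(allowed_blocks)) {
    bad <- setdiff(names(cfg[[blk]]), allowed_blocks[[blk]])
    if (length(bad))
      stop("unknown key(s) in config block '", blk, "': ",
           paste(bad, collapse = ", "))
  }
  merged <- utils::modifyList(def, cfg)
  sc <- merged$experiment$scenario
  if (!sc %in% c("homogeneous", "two_special", "lognormal_ensemble", "cell_cycle"))
    stop("unknown scenario: ", sc)
  merged$hash <- config_hash(merged[setdiff(names(merged), "hash")])
  merged
}

## Scenario driver -------------------------------------------------------------

scenario_genome <- function(cfg) {
  gcfg <- cfg$genome
  if (!is.null(gcfg$path)) return(read_genome(gcfg$path))
  args <- gcfg[setdiff(names(gcfg), "path")]
  args$seed <- args$seed %||% derive_seed(cfg$seed, 1L)
  sc <- cfg$experiment$scenario
  if (sc == "homogeneous") {
    args$K_cv <- 0
    args$lifetime_cv <- 0
  } else if (sc %in% c("two_special", "cell_cycle")) {
    args$K_cv <- 0
    args$lifetime_cv <- 0
    args$lifetime_mean <- args$lifetime_mean %||% 1
    mult <- cfg$experiment$special_multipliers
    args$special_overrides <- stats::setNames(as.numeric(mult),
                                              c("gene_0001", "gene_0002"))
  }
  do.call(make_genome, args)
}

#' Run one of the canonical simulation scenarios end to end
#'
#' Generates (or loads) the genome, calibrates it, simulates the
#' volume-growth protocol (or the periodic cell cycle), evaluates the theory
#' predictions, fits the nonlinear degrees, and writes the output bundle:
#' `genome.tsv`, `trajectory.tsv`, `predictions.tsv`, `estimates.tsv` and
#' `summary.json`, every file carrying the config hash and seed. Scenarios:
#' `homogeneous` (all recruitment abilities equal - the linear-scaling
#' baseline), `two_special` (two genes at `special_multipliers` times the
#' background MM constant), `lognormal_ensemble` (continuously distributed
#' abilities) and `cell_cycle` (ratio-triggered division with the two
#' special genes as reporters).
#'
#' @param config config list or path to a JSON config (see
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed); `NULL` skips file
#'   output.
#' @return the summary list, invisibly when writing files.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_run_config(config)
  globals <- do.call(global_params, cfg$globals)
  genome <- scenario_genome(cfg)
  meta <- list(config_hash = cfg$hash, seed = cfg$seed, version = pkg_version())
  ex <- cfg$experiment
  sc <- ex$scenario

  summary <- list(scenario = sc, seed = cfg$seed, config_hash = cfg$hash)

  if (sc == "cell_cycle") {
    cal <- calibrate(genome, globals)
    thr <- ex$ratio_threshold
    if (is.null(thr)) {
      ## pick a reachable trigger: the reporter ratio halfway to the mass stop
      pre <- run_experiment(genome, globals, burn_in = ex$burn_in,
                            t_end = ex$t_end, stop_multiplier = ex$stop_multiplier,
                            dt_out = ex$dt_out, meta = meta)
      mid <- floor((pre$origin + length(pre$time)) / 2)
      thr <- pre$p[mid, "gene_0001"] / pre$p[mid, "gene_0002"]
    }
    cyc <- run_cell_cycle(genome, globals, "gene_0001", "gene_0002",
                          ratio_threshold = thr, n_cycles = ex$n_cycles,
                          dt_out = ex$dt_out)
    summary$ratio_threshold <- thr
    summary$n_cycles <- nrow(cyc$cycles)
    summary$converged <- cyc$converged
    summary$degenerate <- cyc$degenerate
    summary$max_fold_dev_last_cycle <- cyc$cycles$max_fold_dev[nrow(cyc$cycles)]
    summary$cycle_length <- cyc$cycles$length[nrow(cyc$cycles)]
    result <- list(cycle = cyc)
  } else {
    traj <- run_experiment(genome, globals, burn_in = ex$burn_in,
                           t_end = ex$t_end, stop_multiplier = ex$stop_multiplier,
                           dt_out = ex$dt_out, meta = meta)
    pred <- predict_scaling(traj)
    est <- fit_trajectory_betas(traj, n_bins = cfg$fit$n_bins,
                                weights = cfg$fit$weights)
    tab <- as_expression_table(traj, "mRNA", n_bins = cfg$fit$n_bins)
    rates <- production_rate_proxy(tab$expression[, 1], traj$genome$tau_m)
    merged <- merge(est, pred, by = "gene_id", sort = FALSE)
    gen <- merged[traj$genome$role[match(merged$gene_id, traj$genome$gene_id)] == "generic", ]

    summary$n0_over_nc <- attr(pred, "n0_over_nc")
    summary$K_avg <- attr(pred, "K_avg")
    summary$max_abs_beta <- max(abs(gen$beta_hat))
    summary$median_beta <- stats::median(gen$beta_hat)
    summary$iqr_beta <- stats::IQR(gen$beta_hat)
    if (sc == "two_special") {
      sp <- merged[merged$gene_id %in% c("gene_0001", "gene_0002"), ]
      summary$special <- sp[, c("gene_id", "K_n", "beta_hat", "beta_pred")]
    }
    if (stats::sd(gen$beta_pred) > 0) {
      reg <- stats::lm(beta_hat ~ beta_pred, data = gen)
      summary$theory_slope <- unname(stats::coef(reg)[2])
      summary$theory_r2 <- summary.lm.r2(reg)
    }
    ok <- gen$converged & !is.na(rates[gen$gene_id])
    if (sum(ok) >= 10 && stats::sd(gen$beta_hat[ok]) > 0) {
      ss <- scaling_summary(gen[ok, ], rates[gen$gene_id[ok]])
      summary$spearman_beta_rate <- ss$spearman$estimate
      summary$pearson_beta_rate <- ss$pearson$estimate
    }
    result <- list(trajectory = traj, predictions = pred, estimates = est,
                   rates = rates)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genome(if (sc == "cell_cycle") result$cycle$genome else result$trajectory$genome,
                 file.path(out_dir, "genome.tsv"), meta = meta)
    if (sc != "cell_cycle") {
      write_trajectory(result$trajectory, file.path(out_dir, "trajectory.tsv"),
                       meta = meta)
      utils::write.table(result$predictions, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(result$estimates, file.path(out_dir, "estimates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      utils::write.table(result$cycle$cycles, file.path(out_dir, "cycles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(c(summary, result)))
  }
  c(summary, result)
}

summary.lm.r2 <- function(fit) {
  s <- stats::summary.lm(fit)
  s$r.squared
}
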