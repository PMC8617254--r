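#' Validate a gene-parameter table
#'
#' A genome is a `data.frame` with one row per coarse-grained gene and columns
#' `gene_id`, `role` (one of `"rnap"`, `"ribosome"`, `"generic"`), `L` (length
#' in codons), `g` (gene copy number), `K_n` and `K_r` (Michaelis-Menten
#' constants for RNAP/ribosome binding, molecules/um^3), `Gamma_n` and
#' `Gamma_r` (transcription/translation initiation rates, 1/min), `tau_m`
#' (mRNA lifetime, min) and `tau_p` (protein lifetime, min; `Inf` means
#' nondegradable). `Gamma_n` may be `NA` on an uncalibrated genome; it is
#' fixed by [calibrate()]. An optional `gamma_mult` column carries the
#' lognormal initiation-rate multipliers of heterogeneous-`Gamma` genomes.
#'
#' @param genome data.frame as described above.
#' @return `genome`, invisibly, with class `volscale_genome` prepended.
#' @export
validate_genome <- function(genome) {
  req <- c("gene_id", "role", "L", "g", "K_n", "K_r",
           "Gamma_n", "Gamma_r", "tau_m", "tau_p")
  miss <- setdiff(req, names(genome))
  if (length(miss))
    stop("genome table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (anyDuplicated(genome$gene_id))
    stop("duplicated gene_id in genome table")
  if (!all(genome$role %in% c("rnap", "ribosome", "generic")))
    stop("role must be one of 'rnap', 'ribosome', 'generic'")
  if (sum(genome$role == "rnap") != 1L)
    stop("exactly one gene must have role 'rnap'")
  if (sum(genome$role == "ribosome") != 1L)
    stop("exactly one gene must have role 'ribosome'")
  pos <- c("L", "g", "K_n", "K_r", "tau_m")
  for (col in pos) {
    v <- genome[[col]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop("column '", col, "' must be strictly positive and finite")
  }
  gr <- genome$Gamma_r
  if (!is.numeric(gr) || any(!is.finite(gr)) || any(gr < 0))
    stop("column 'Gamma_r' must be finite and nonnegative")
  if (any(genome$tau_p <= 0, na.rm = TRUE) || any(is.na(genome$tau_p)))
    stop("column 'tau_p' must be positive (Inf allowed for nondegradable)")
  gn <- genome$Gamma_n
  if (!all(is.na(gn))) {
    ## zero is legal (a silent gene holds no elongation slots); NA means
    ## "uncalibrated" and must then hold for every gene
    if (any(is.na(gn)) || any(!is.finite(gn)) || any(gn < 0))
      stop("column 'Gamma_n' must be all NA (uncalibrated) or all nonnegative")
  }
  if (!is.null(genome$gamma_mult)) {
    if (any(!is.finite(genome$gamma_mult)) || any(genome$gamma_mult <= 0))
      stop("column 'gamma_mult' must be strictly positive")
  }
  if (!inherits(genome, "volscale_genome"))
    class(genome) <- c("volscale_genome", class(genome))
  invisible(genome)
}

#' Generate a synthetic genome with lognormal recruitment abilities
#'
#' Draws a gene-parameter table emulating the statistical structure used in
#' the whole-cell simulations: `n_genes` coarse-grained genes including one
#' RNAP gene and one ribosome gene, transcriptional Michaelis-Menten
#' constants `K_n` lognormal with arithmetic mean `K_mean` and coefficient of
#' variation `K_cv`, mRNA lifetimes lognormal with mean `lifetime_mean` and
#' CV `lifetime_cv`, gene copy number 1 for every gene except the ribosome
#' gene (copy number 5). The RNAP and ribosome genes take the average `K_n`
#' of the generic draws, computed as the self-consistent mass-fraction
#' weighted average (weights proportional to the steady-state protein mass
#' \eqn{g_i \tau_{m,i} L_i} under low promoter occupancy, i.e.
#' \eqn{\sum S_i / \sum S_i/K_i}): this places both machinery genes at the
#' sublinear/superlinear pivot so the polymerase pools scale linearly with
#' volume and the cell stays in Phase 1 over the whole 9-fold growth range.
#' `special_overrides` pins selected generic genes to
#' `multiplier * K_mean`, the construction behind the two-special-genes
#' scenario (multipliers 20 and 0.2).
#'
#' Transcription initiation rates are left `NA`; they are fixed by
#' [calibrate()] so that the realized critical RNAP number hits the attempted
#' `n_c`. With `gamma_cv > 0` a unit-mean lognormal multiplier is attached to
#' each generic gene (column `gamma_mult`) and applied to the calibrated
#' rates, modelling promoter-to-promoter heterogeneity in initiation; the
#' multipliers are renormalised during calibration so the realized `n_c` is
#' unchanged.
#'
#' @param n_genes total number of genes (>= 3).
#' @param K_mean,K_cv arithmetic mean (molecules/um^3) and CV of the
#'   transcriptional MM constants.
#' @param lifetime_mean,lifetime_cv arithmetic mean (min) and CV of the mRNA
#'   lifetimes.
#' @param special_overrides named numeric vector: `gene_id -> multiplier`;
#'   each named gene gets `K_n = multiplier * K_mean`. Generic gene ids are
#'   `"gene_0001", ...`. Overriding the rnap/ribosome genes is an error
#'   (their linear scaling is a model assumption).
#' @param gamma_cv CV of the lognormal initiation-rate multipliers (0 =
#'   homogeneous initiation rates).
#' @param n_degradable number of generic genes given a finite protein
#'   lifetime `tau_p_deg`; all other proteins are nondegradable.
#' @param tau_p_deg protein lifetime (min) of the degradable subset.
#' @param seed integer seed; the same seed yields a bit-identical genome.
#' @param length_mean,length_cv arithmetic mean (codons) and CV of generic
#'   gene lengths.
#' @param L_rnap,L_ribosome lengths of the coarse-grained RNAP and ribosome
#'   genes, codons.
#' @param K_r translational MM constant, molecules/um^3 (shared).
#' @param Gamma_r translation initiation rate, 1/min (shared).
#' @return A `volscale_genome` data.frame (uncalibrated: `Gamma_n` is `NA`).
#' @examples
#' g <- make_genome(50, K_cv = 0, seed = 1)
#' all(g$K_n == 6e3)
#' @export
make_genome <- function(n_genes, K_mean = 6e3, K_cv = 0.5,
                        lifetime_mean = 10, lifetime_cv = 1,
                        special_overrides = NULL, gamma_cv = 0,
                        n_degradable = 0, tau_p_deg = 10, seed,
                        length_mean = 500, length_cv = 0.3,
                        L_rnap = 5000, L_ribosome = 10000,
                        K_r = 6e3, Gamma_r = 60) {
  if (missing(seed)) stop("'seed' is required for a reproducible genome")
  if (n_genes < 3) stop("need at least 3 genes (rnap, ribosome, one generic)")
  stopifnot(K_mean > 0, K_cv >= 0, lifetime_mean > 0, lifetime_cv >= 0,
            gamma_cv >= 0, tau_p_deg > 0, length_mean > 0, length_cv >= 0,
            L_rnap > 0, L_ribosome > 0, K_r > 0, Gamma_r > 0)
  n_gen <- n_genes - 2L
  if (n_degradable < 0 || n_degradable > n_gen)
    stop("'n_degradable' must be between 0 and n_genes - 2")

  with_seed(seed, {
    L <- pmax(3, round(rlnorm_meancv(n_gen, length_mean, length_cv)))
    K <- rlnorm_meancv(n_gen, K_mean, K_cv)
    tau_m <- rlnorm_meancv(n_genes, lifetime_mean, lifetime_cv)
    gamma_mult <- if (gamma_cv > 0) rlnorm_meancv(n_gen, 1, gamma_cv) else rep(1, n_gen)
    deg <- if (n_degradable > 0) sample.int(n_gen, n_degradable) else integer(0)

    ids <- c("rnap", "ribosome", sprintf("gene_%04d", seq_len(n_gen)))
    ## machinery K at the self-consistent pivot <K> of the generic draws,
    ## before any special overrides (the specials are perturbations and do
    ## not define the background average)
    S <- tau_m[-(1:2)] * L * gamma_mult
    K_machinery <- sum(S) / sum(S / K)
    K_n <- c(K_machinery, K_machinery, K)
    if (!is.null(special_overrides) && length(special_overrides)) {
      if (is.null(names(special_overrides)) || any(names(special_overrides) == ""))
        stop("'special_overrides' must be a named numeric vector")
      if (any(names(special_overrides) %in% c("rnap", "ribosome")))
        stop("cannot override K_n of the rnap/ribosome genes: ",
             "their linear scaling is a model assumption")
      hit <- match(names(special_overrides), ids)
      if (anyNA(hit))
        stop("unknown gene_id in special_overrides: ",
             paste(names(special_overrides)[is.na(hit)], collapse = ", "))
      if (any(special_overrides <= 0)) stop("override multipliers must be positive")
      K_n[hit] <- special_overrides * K_mean
    }

    tau_p <- rep(Inf, n_genes)
    tau_p[2L + deg] <- tau_p_deg

    genome <- data.frame(
      gene_id = ids,
      role = c("rnap", "ribosome", rep("generic", n_gen)),
      L = c(L_rnap, L_ribosome, L),
      g = c(1, 5, rep(1, n_gen)),
      K_n = K_n,
      K_r = K_r,
      Gamma_n = NA_real_,
      Gamma_r = Gamma_r,
      tau_m = tau_m,
      tau_p = tau_p,
      gamma_mult = c(1, 1, gamma_mult),
      stringsAsFactors = FALSE
    )
    validate_genome(genome)
    genome
  })
}

## Gene-table TSV dialect ------------------------------------------------------
## UTF-8, tab-separated, "." decimal, "inf" for infinite lifetimes, leading
## "# key=value" comment lines. Lossless at (better than) 12 significant digits.

#' Write a genome to TSV
#'
#' @param genome a `volscale_genome`.
#' @param path output file.
#' @param meta named character/list written as leading `# key=value` lines.
#' @export
write_genome <- function(genome, path, meta = list()) {
  validate_genome(genome)
  cols <- c("gene_id", "role", "L", "g", "K_n", "K_r",
            "Gamma_n", "Gamma_r", "tau_m", "tau_p")
  if (!is.null(genome$gamma_mult) && any(genome$gamma_mult != 1))
    cols <- c(cols, "gamma_mult")
  num <- setdiff(cols, c("gene_id", "role"))
  out <- as.data.frame(genome)[, cols, drop = FALSE]
  for (col in num) out[[col]] <- fmt_num(out[[col]])
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_header(meta), con)
  writeLines(paste(cols, collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}

#' Read a genome from TSV
#'
#' Malformed rows are reported with their line numbers; a missing required
#' column is an error naming the column.
#'
#' @param path TSV file written by [write_genome()] or conforming to the same
#'   dialect.
#' @return A `volscale_genome` data.frame.
#' @export
read_genome <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  if (!length(body_idx)) stop("empty genome file: ", path)
  header <- strsplit(lines[body_idx[1]], "\t", fixed = TRUE)[[1]]
  req <- c("gene_id", "role", "L", "g", "K_n", "K_r",
           "Gamma_n", "Gamma_r", "tau_m", "tau_p")
  miss <- setdiff(req, header)
  if (length(miss))
    stop("genome file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  rows <- body_idx[-1]
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(header))
  if (length(bad))
    stop("malformed genome row(s) at line(s) ",
         paste(rows[bad], collapse = ", "), " in ", path)
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  genome <- data.frame(gene_id = mat[, "gene_id"], role = mat[, "role"],
                       stringsAsFactors = FALSE)
  for (col in setdiff(header, c("gene_id", "role")))
    genome[[col]] <- parse_num(mat[, col])
  if (is.null(genome$gamma_mult)) genome$gamma_mult <- 1
  validate_genome(genome)
  genome
}
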