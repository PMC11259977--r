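#' Age interval (credibility interval on a node age)
#'
#' @param older,younger Bounds in Ma, `older >= younger`.
#' @param label Optional label.
#' @return An object of class `age_interval`.
#' @export
age_interval <- function(older, younger, label = "") {
  if (older < younger) stop("older bound must be >= younger bound")
  structure(list(older = older, younger = younger, label = label),
            class = "age_interval")
}

# exact arithmetic at the printed 2-decimal precision (integer hundredths)
cents <- function(x) round(x * 100)

#' Interval width and pairwise offset range
#'
#' Width of `a`, and -- when `b` is given -- the offset range between the
#' two intervals: (minimum gap, maximum gap) = (a.younger - b.older,
#' a.older - b.younger). Arithmetic is exact at 2 decimal places (the
#' printed precision of age estimates in Ma).
#'
#' @param a An [age_interval()].
#' @param b Optional second [age_interval()].
#' @return List with `width` and, if `b` is given, `offset` (length 2:
#'   min gap, max gap) and `width_b`.
#' @export
interval_stats <- function(a, b = NULL) {
  stopifnot(inherits(a, "age_interval"))
  out <- list(width = (cents(a$older) - cents(a$younger)) / 100)
  if (!is.null(b)) {
    stopifnot(inherits(b, "age_interval"))
    out$width_b <- (cents(b$older) - cents(b$younger)) / 100
    out$offset <- c(min_gap = (cents(a$younger) - cents(b$older)) / 100,
                    max_gap = (cents(a$older) - cents(b$younger)) / 100)
  }
  out
}

#' Infinite-sites regression of HPD width on posterior mean age
#'
#' Ordinary least squares of the 95% HPD interval width on the posterior
#' mean age, both in 100-Myr units. As data accumulate the slope of this
#' regression falls toward the infinite-sites limit, where only the
#' calibration uncertainty remains; the slope reads as "Myr of credible
#' interval added per Myr of divergence". Reported with and without the
#' root node when the root is identified.
#'
#' @param points Data frame with columns `mean` and `width` (100 Myr
#'   units) and optionally `node`/`label`.
#' @param root Optional index (or logical vector) marking the root row.
#' @return Data frame with one row per subset (`with_root`,
#'   `without_root`, or `all`): `slope`, `intercept`, `r2`, `rse`, `n`.
#' @export
infinite_sites_regression <- function(points, root = NULL) {
  stopifnot(is.data.frame(points), all(c("mean", "width") %in% names(points)))
  fit_one <- function(df, name) {
    if (nrow(df) < 3) stop("need at least 3 points for the regression")
    fit <- lm(width ~ mean, data = df)
    s <- suppressWarnings(summary(fit)) # exact fits are legitimate here
    data.frame(subset = name, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               r2 = s$r.squared, rse = s$sigma, n = nrow(df),
               stringsAsFactors = FALSE)
  }
  if (is.null(root)) return(fit_one(points, "all"))
  root_mask <- if (is.logical(root)) root else
    seq_len(nrow(points)) %in% root
  rbind(fit_one(points, "with_root"),
        fit_one(points[!root_mask, , drop = FALSE], "without_root"))
}

#' Compare per-node posterior means between two clock models
#'
#' Paired two-tailed t-test on per-node posterior mean differences plus the
#' regression of one set of means on the other. With all differences equal
#' the t statistic is degenerate: equal means give `t = 0, P = 1` by
#' convention; equal nonzero differences give an undefined P with a
#' `degenerate` flag.
#'
#' @param means_a,means_b Numeric vectors of per-node posterior means over
#'   the same node set (same order).
#' @return List with `t`, `p`, `df`, `degenerate`, and `regression`
#'   (intercept, slope of a on b).
#' @export
compare_clock_models <- function(means_a, means_b) {
  if (length(means_a) != length(means_b))
    stop("mean vectors differ in length")
  n <- length(means_a)
  if (n < 2) stop("need at least 2 shared nodes")
  d <- means_a - means_b
  reg <- coef(lm(means_a ~ means_b))
  if (var(d) == 0) {
    if (all(d == 0))
      return(list(t = 0, p = 1, df = n - 1L, degenerate = TRUE,
                  regression = reg))
    return(list(t = sign(mean(d)) * Inf, p = NA_real_, df = n - 1L,
                degenerate = TRUE, regression = reg))
  }
  tstat <- mean(d) / (sd(d) / sqrt(n))
  list(t = tstat, p = 2 * pt(-abs(tstat), df = n - 1), df = n - 1L,
       degenerate = FALSE, regression = reg)
}

read_design_file <- function(path) {
  kv <- utils::read.delim(path, header = FALSE,
                          col.names = c("key", "value"),
                          stringsAsFactors = FALSE)
  out <- as.list(kv$value)
  names(out) <- kv$key
  out$duplicated_taxa <- strsplit(out$duplicated_taxa, ",")[[1]]
  out$outgroup_taxa <- strsplit(out$outgroup_taxa, ",")[[1]]
  out$copy_suffixes <- strsplit(out$copy_suffixes, ",")[[1]]
  out
}

#' Run the full dating pipeline on an on-disk study
#'
#' Orchestrates: conformance screening of the per-locus gene trees, length
#' filtering and concatenation, per-locus branch-length approximation
#' (estimated from the alignments, or read from an existing BV file),
#' dating runs for nested locus subsets (sequentially concatenated in a
#' seeded random order) under the requested clock(s), duplicate-seed
#' convergence checking on the full dataset, the infinite-sites table and
#' regression, and the WGD-to-crown-radiation interval report. All outputs
#' are CSV/TSV under `out_dir` together with an md5 manifest.
#'
#' @param config List with elements: `fixture_dir` (study directory as laid
#'   out by [make_fixture()]), `out_dir`, and optionally `clocks` (default
#'   `"ILN"`), `subsets` (locus counts; 0 = prior-only; default
#'   `c(0, 1, 6, 12, 18, 30)` capped at the available loci), `n_iter`,
#'   `min_len` (default 100), `seed`, `bv_path` (reuse a BV file),
#'   `subst_model`, `gamma_k`, `gamma_shape`.
#' @return Invisibly, a list with the screen report, concatenation summary,
#'   posterior summaries per clock and subset, convergence report,
#'   infinite-sites table/regressions, interval report, and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- config
  stopifnot(!is.null(cfg$fixture_dir), !is.null(cfg$out_dir))
  if (is.null(cfg$clocks)) cfg$clocks <- "ILN"
  if (is.null(cfg$n_iter)) cfg$n_iter <- 6000L
  if (is.null(cfg$min_len)) cfg$min_len <- 100L
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  run <- function(stage_name, expr) {
    stage <<- stage_name
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed [",
           basename(cfg$fixture_dir), "]: ", conditionMessage(e),
           call. = FALSE))
  }

  des <- run("read_design",
             read_design_file(file.path(cfg$fixture_dir, "design.tsv")))
  sp <- run("read_trees",
            parse_newick(paste(readLines(
              file.path(cfg$fixture_dir, "species_tree.nwk")),
              collapse = "")))
  dup <- build_duplicated_topology(sp, des$duplicated_taxa,
                                   des$copy_suffixes)
  ctab <- read_calibration_table(file.path(cfg$fixture_dir,
                                           "calibrations.tsv"))
  cal <- calibrations_for_tree(dup, ctab)

  ## screen ----------------------------------------------------------------
  loci_files <- sort(list.files(file.path(cfg$fixture_dir, "loci"),
                                full.names = TRUE))
  gt_files <- file.path(cfg$fixture_dir, "gene_trees",
                        sub("\\.fasta$", ".nwk", basename(loci_files)))
  screen <- run("screen", {
    rows <- lapply(seq_along(loci_files), function(i) {
      gt <- parse_newick(paste(readLines(gt_files[i]), collapse = ""),
                         strict = FALSE)
      v <- screen_orthogroup(gt, dup)
      data.frame(locus = sub("\\.fasta$", "", basename(loci_files[i])),
                 pass = v$pass, reason = v$reason, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  write.csv(screen, file.path(cfg$out_dir, "screen_report.csv"),
            row.names = FALSE)

  ## concat ----------------------------------------------------------------
  loci <- run("read_loci", lapply(loci_files[screen$pass], read_locus_fasta))
  oset <- run("concat",
              filter_and_concatenate(loci, min_len = cfg$min_len,
                                     roster = dup$phy$tip.label))
  write.csv(as.data.frame(oset$summary),
            file.path(cfg$out_dir, "concat_summary.csv"), row.names = FALSE)

  ## branch-length approximations ------------------------------------------
  bv <- run("bv", {
    if (!is.null(cfg$bv_path)) read_bv(cfg$bv_path)
    else {
      model <- aa_model(if (!is.null(cfg$subst_model)) cfg$subst_model
                        else des$subst_model,
                        gamma_k = if (is.null(cfg$gamma_k)) 1L else
                          cfg$gamma_k,
                        gamma_shape = cfg$gamma_shape)
      lapply(oset$loci, function(aln) {
        sub <- ape::drop.tip(dup$phy,
                             setdiff(dup$phy$tip.label, names(aln$seqs)))
        estimate_brlens_and_hessian(aln, sub, model)
      })
    }
  })
  bv_file <- file.path(cfg$out_dir, "loci.bv")
  write_bv(bv, bv_file)
  # dating uses complete loci only (partial loci would need per-locus trees)
  full <- vapply(bv, function(a) setequal(a$tips, dup$phy$tip.label),
                 logical(1))
  bv_full <- bv[full]

  n_avail <- length(bv_full)
  subsets <- if (is.null(cfg$subsets)) c(0, 1, 6, 12, 18, 30) else cfg$subsets
  subsets <- sort(unique(pmin(subsets, n_avail)))
  set.seed(cfg$seed)
  locus_order <- sample.int(n_avail)

  ## dating ----------------------------------------------------------------
  summaries <- list()
  results <- list()
  for (clk in cfg$clocks) {
    for (k in subsets) {
      tag <- paste0(clk, "_k", k)
      ps <- run(paste0("date_", tag),
                run_chain(dup, bv_full[locus_order[seq_len(k)]],
                          clock = clock_config(clk),
                          calibrations = cal, n_iter = cfg$n_iter,
                          seed = cfg$seed + k,
                          use_likelihood = k > 0))
      sm <- summarize_posterior(ps)
      sm$clock <- clk
      sm$n_loci <- k
      summaries[[tag]] <- sm
      results[[tag]] <- ps
      write.csv(sm, file.path(cfg$out_dir, paste0("summary_", tag, ".csv")),
                row.names = FALSE)
    }
  }

  ## convergence on the full dataset ----------------------------------------
  kmax <- max(subsets)
  conv <- run("convergence", {
    ps2 <- run_chain(dup, bv_full[locus_order[seq_len(kmax)]],
                     clock = clock_config(cfg$clocks[1]),
                     calibrations = cal, n_iter = cfg$n_iter,
                     seed = cfg$seed + 10000L, use_likelihood = kmax > 0)
    check_convergence(results[[paste0(cfg$clocks[1], "_k", kmax)]], ps2)
  })
  write.csv(conv, file.path(cfg$out_dir, "convergence_report.csv"),
            row.names = FALSE)

  ## infinite-sites table ----------------------------------------------------
  isp <- run("infinite_sites", {
    rows <- lapply(names(summaries), function(tag) {
      sm <- summaries[[tag]]
      age <- sm[startsWith(sm$param, "t_n"), ]
      data.frame(clock = sm$clock[1], n_loci = sm$n_loci[1],
                 param = age$param, label = age$label,
                 mean = ma_to_unit(age$mean),
                 width = ma_to_unit(age$upper - age$lower))
    })
    do.call(rbind, rows)
  })
  write.csv(isp, file.path(cfg$out_dir, "infinite_sites_points.csv"),
            row.names = FALSE)
  root_param <- paste0("t_n", ape::Ntip(dup$phy) + 1L)
  isreg <- do.call(rbind, lapply(split(isp, list(isp$clock, isp$n_loci)),
    function(df) {
      if (nrow(df) < 3) return(NULL)
      r <- infinite_sites_regression(df, root = df$param == root_param)
      r$clock <- df$clock[1]; r$n_loci <- df$n_loci[1]
      r
    }))
  write.csv(isreg, file.path(cfg$out_dir, "infinite_sites_regression.csv"),
            row.names = FALSE)

  ## interval report ---------------------------------------------------------
  interval_report <- run("intervals", {
    tag <- paste0(cfg$clocks[1], "_k", kmax)
    sm <- summaries[[tag]]
    wgd_node <- attr(dup, "wgd_node")
    wgd_row <- sm[sm$param == paste0("t_n", wgd_node), ]
    wgd_int <- age_interval(round(wgd_row$upper, 2),
                            round(wgd_row$lower, 2), "WGD")
    kids <- dup$phy$edge[dup$phy$edge[, 1] == wgd_node, 2]
    rep_rows <- lapply(kids, function(n) {
      cr <- sm[sm$param == paste0("t_n", n), ]
      st <- interval_stats(wgd_int, age_interval(round(cr$upper, 2),
                                                 round(cr$lower, 2)))
      data.frame(node = n, wgd_width = st$width,
                 crown_width = st$width_b,
                 min_gap = st$offset["min_gap"],
                 max_gap = st$offset["max_gap"])
    })
    do.call(rbind, rep_rows)
  })
  write.csv(interval_report, file.path(cfg$out_dir, "interval_report.csv"),
            row.names = FALSE)

  ## manifest ----------------------------------------------------------------
  outs <- sort(list.files(cfg$out_dir, full.names = TRUE, pattern = "\\.(csv|bv)$"))
  outs <- outs[basename(outs) != "manifest.tsv"]
  manifest <- data.frame(file = basename(outs),
                         md5 = unname(tools::md5sum(outs)),
                         stringsAsFactors = FALSE)
  write_lines_bin(c("file\tmd5",
                    paste(manifest$file, manifest$md5, sep = "\t")),
                  file.path(cfg$out_dir, "manifest.tsv"))

  invisible(list(screen = screen, concat = oset$summary,
                 summaries = summaries, convergence = conv,
                 infinite_sites = isp, regressions = isreg,
                 intervals = interval_report, manifest = manifest,
                 bv_file = bv_file))
}
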