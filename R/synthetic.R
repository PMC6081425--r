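# Seed-reproducible generators for every input the pipeline consumes,
# with planted ground truth, plus a saturable TDMD kinetics simulator.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  expr
}

#' Generate a synthetic TargetScan-style prediction table
#'
#' Draws miRNA:target pairs with 3C-scores sampled per class. The default
#' class probabilities emulate a genome-scale prediction table in which
#' roughly 15% of interactions carry a 3C site and under 1% fall in the
#' HIGH class.
#'
#' @param n_pairs Number of rows.
#' @param class_probs Named probabilities over NONE/LOW/MID/HIGH (sum 1).
#' @param n_mirnas,n_genes Label pool sizes.
#' @param seed RNG seed (bit-for-bit reproducible).
#' @return data.frame with columns `gene`, `mirna`, `site_type`,
#'   `conserved`, `c3_score`.
#' @export
gen_targetscan_table <- function(n_pairs,
                                 class_probs = c(NONE = 0.85, LOW = 0.10,
                                                 MID = 0.042, HIGH = 0.008),
                                 n_mirnas = 20L, n_genes = NULL,
                                 seed = NULL) {
  stopifnot(abs(sum(class_probs) - 1) < 1e-8)
  if (n_pairs == 0) {
    return(data.frame(gene = character(0), mirna = character(0),
                      site_type = character(0), conserved = logical(0),
                      c3_score = numeric(0), stringsAsFactors = FALSE))
  }
  if (is.null(n_genes)) n_genes <- max(50L, ceiling(n_pairs / n_mirnas))
  .with_seed(seed, {
    cls <- sample(names(class_probs), n_pairs, replace = TRUE,
                  prob = class_probs)
    lo <- c(NONE = -0.0099, LOW = -0.0299, MID = -0.0499, HIGH = -0.15)
    hi <- c(NONE = 0, LOW = -0.0101, MID = -0.0301, HIGH = -0.0501)
    data.frame(
      gene = sprintf("Gene%05d", sample.int(n_genes, n_pairs, replace = TRUE)),
      mirna = sprintf("miR-sim-%02d",
                      sample.int(n_mirnas, n_pairs, replace = TRUE)),
      site_type = sample(c("8mer", "7mer-m8", "7mer-A1", "6mer"), n_pairs,
                         replace = TRUE, prob = c(0.15, 0.25, 0.25, 0.35)),
      conserved = sample(c(TRUE, FALSE), n_pairs, replace = TRUE),
      c3_score = stats::runif(n_pairs, lo[cls], hi[cls]),
      stringsAsFactors = FALSE)
  })
}

#' Describe a serum-stimulation scenario
#'
#' Parameters of the synthetic serum time course: one massively induced
#' transcript dominating the HIGH-class 3C pool of its miRNAs, over a
#' log-normal background. Defaults emulate the fibroblast serum response:
#' induction peaking at 2 h above 1000 RPKM with a maximum log2
#' fold-change of 6.92 against the quiescent (0 h) state, and a planted
#' HIGH pool share above 90% at the peak.
#'
#' @param timepoints Hours after serum addition (first is the reference).
#' @param induced_gene,induced_mirnas The planted TDMD pair(s).
#' @param peak_rpkm,peak_time,induced_log2fc Induction amplitude and shape.
#' @param n_background Background gene count.
#' @param bg_meanlog,bg_sdlog Log-normal background RPKM parameters.
#' @param n_competing_high Number of other HIGH-class targets of the
#'   induced miRNAs (kept lowly expressed).
#' @param mirna_cpm Named baseline CPM of the miRNA panel; filled with a
#'   default panel when `NULL`.
#' @param noise_sd Multiplicative log-normal noise (sdlog) on expression;
#'   0 gives exactly the scenario means.
#' @param pseudocount Pseudocount used when back-computing the baseline
#'   from the planted log2 fold-change.
#' @return List of class `"serum_scenario"`.
#' @export
serum_scenario <- function(timepoints = c(0, 1, 2, 4, 8, 12),
                           induced_gene = "Serpine1",
                           induced_mirnas = c("miR-30c-5p", "miR-30b-5p"),
                           peak_rpkm = 1200, peak_time = 2,
                           induced_log2fc = 6.92,
                           n_background = 300L,
                           bg_meanlog = 2.5, bg_sdlog = 1.5,
                           n_competing_high = 5L,
                           mirna_cpm = NULL, noise_sd = 0.1,
                           pseudocount = 0.1) {
  if (is.null(mirna_cpm)) {
    mirna_cpm <- c("miR-30a-5p" = 300, "miR-30b-5p" = 400,
                   "miR-30c-5p" = 200, "miR-30d-5p" = 250,
                   "miR-30e-5p" = 80, "let-7b-5p" = 1500,
                   "miR-21a-5p" = 5000, "miR-224-5p" = 2,
                   "miR-320-3p" = 5)
  }
  structure(as.list(environment()), class = "serum_scenario")
}

# dimensionless induction pulse: 0 at t = 0, 1 at t = peak_time
.pulse <- function(t, peak_time) {
  (t / peak_time * exp(1 - t / peak_time))^2
}

#' Generate a synthetic serum time course
#'
#' Realises a [serum_scenario()]: a gene RPKM matrix across the time
#' course, a miRNA CPM matrix, and a target table in which the induced
#' transcript is a HIGH-class 3C-target of the induced miRNAs while
#' competing HIGH targets stay lowly expressed. Ground truth (planted
#' fold-change and expected pool dominance) is returned for bookkeeping.
#'
#' @param scenario A [serum_scenario()].
#' @param seed RNG seed; equal seeds give identical output.
#' @return List with `gene_expr` (RPKM matrix), `mirna_expr` (CPM matrix),
#'   `targets` (TargetScan-style data.frame) and `truth`.
#' @export
gen_serum_timecourse <- function(scenario = serum_scenario(), seed = NULL) {
  stopifnot(inherits(scenario, "serum_scenario"))
  sc <- scenario
  .with_seed(seed, {
    tp <- sc$timepoints
    cn <- paste0(tp, "h")
    pc <- sc$pseudocount
    baseline <- (sc$peak_rpkm + pc) / 2^sc$induced_log2fc - pc
    induced <- baseline +
      (sc$peak_rpkm - baseline) * .pulse(tp, sc$peak_time)

    bg_names <- sprintf("Gene%05d", seq_len(sc$n_background))
    bg_base <- stats::rlnorm(sc$n_background, sc$bg_meanlog, sc$bg_sdlog)
    gene_expr <- matrix(rep(bg_base, length(tp)), ncol = length(tp),
                        dimnames = list(bg_names, cn))
    comp_names <- sprintf("CompHigh%02d", seq_len(sc$n_competing_high))
    comp_base <- stats::runif(sc$n_competing_high, 1, 5)
    gene_expr <- rbind(gene_expr,
                       matrix(rep(comp_base, length(tp)), ncol = length(tp),
                              dimnames = list(comp_names, cn)))
    gene_expr <- rbind(gene_expr,
                       matrix(induced, nrow = 1,
                              dimnames = list(sc$induced_gene, cn)))
    if (sc$noise_sd > 0) {
      gene_expr <- gene_expr *
        matrix(stats::rlnorm(length(gene_expr), 0, sc$noise_sd),
               nrow = nrow(gene_expr))
      # the reference and peak of the planted transcript stay exact so the
      # planted fold-change is recoverable bookkeeping, not a noisy draw
      gene_expr[sc$induced_gene, ] <- induced
    }

    mirna_expr <- matrix(rep(sc$mirna_cpm, length(tp)), ncol = length(tp),
                         dimnames = list(names(sc$mirna_cpm), cn))

    # target table: planted HIGH pairs + competing HIGH pairs + background
    planted <- data.frame(gene = sc$induced_gene, mirna = sc$induced_mirnas,
                          site_type = "8mer", conserved = TRUE,
                          c3_score = -0.12, stringsAsFactors = FALSE)
    competing <- do.call(rbind, lapply(sc$induced_mirnas, function(mi) {
      data.frame(gene = comp_names, mirna = mi, site_type = "7mer-m8",
                 conserved = FALSE,
                 c3_score = stats::runif(length(comp_names), -0.10, -0.0501),
                 stringsAsFactors = FALSE)
    }))
    n_bg_rec <- 5L * sc$n_background
    background <- data.frame(
      gene = sample(bg_names, n_bg_rec, replace = TRUE),
      mirna = sample(names(sc$mirna_cpm), n_bg_rec, replace = TRUE),
      site_type = sample(c("8mer", "7mer-m8", "7mer-A1", "6mer"), n_bg_rec,
                         replace = TRUE),
      conserved = sample(c(TRUE, FALSE), n_bg_rec, replace = TRUE),
      c3_score = -stats::runif(n_bg_rec, 0, 0.0499),
      stringsAsFactors = FALSE)
    background <- background[!duplicated(background[c("gene", "mirna")]), ]
    targets <- rbind(planted, competing, background)

    list(gene_expr = gene_expr, mirna_expr = mirna_expr, targets = targets,
         truth = list(gene = sc$induced_gene, mirnas = sc$induced_mirnas,
                      max_log2fc = sc$induced_log2fc,
                      min_pool_share = 100 * sc$peak_rpkm /
                        (sc$peak_rpkm + sum(comp_base))))
  })
}

#' TDMD kinetics parameters
#'
#' Parameters of the miRNA balance model
#' `dM/dt = sigma - (delta0 + deltaT * T(t) / (T(t) + K)) * M`:
#' constant synthesis `sigma` (copies/h), basal first-order decay `delta0`
#' (1/h), and a saturable (Michaelis-Menten in target abundance)
#' target-directed decay with maximal rate `deltaT` (1/h) and
#' half-saturation `K` (copies per cell). Setting `K` far below the target
#' range makes the TDMD term effectively mass-action-saturated; the
#' saturable form is a modelling choice of this package, not a mechanism
#' taken from measurement.
#'
#' The `"serum"` preset describes a fast miRNA (basal half-life 14 h,
#' steady state 100 cpc) facing a Serpine1-like target pulse (88 cpc
#' rising above 4000 cpc at 2 h); `deltaT` is calibrated, once, so that
#' the miRNA's level halves over the first 4 h of the pulse (the observed
#' net half-life of about 4 h), synthesis included. The `"steady"` preset
#' holds the target constant at 170 cpc with `deltaT` set so that
#' target-directed decay equals basal decay there -- removing the TDMD
#' term then doubles the steady-state miRNA level.
#'
#' @param preset `"serum"`, `"steady"`, or `"none"` (take all values from
#'   the arguments).
#' @param sigma,delta0,deltaT,K,M0 Model parameters (override the preset).
#' @param target Target trajectory: a function of time (h) returning
#'   copies per cell, or a single constant.
#' @return List of class `"tdmd_params"`.
#' @export
tdmd_params <- function(preset = c("serum", "steady", "none"),
                        sigma = NULL, delta0 = NULL, deltaT = NULL,
                        K = NULL, M0 = NULL, target = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    serum = list(M0 = 100, delta0 = log(2) / 14, K = 500,
                 target = function(t) 88 + (4000 - 88) * .pulse(t, 2)),
    steady = list(M0 = 100, delta0 = log(2) / 14, K = 500, target = 170),
    none = list())
  if (!is.null(sigma)) p$sigma <- sigma
  if (!is.null(delta0)) p$delta0 <- delta0
  if (!is.null(deltaT)) p$deltaT <- deltaT
  if (!is.null(K)) p$K <- K
  if (!is.null(M0)) p$M0 <- M0
  if (!is.null(target)) p$target <- target
  if (is.null(p$sigma)) p$sigma <- p$M0 * p$delta0  # basal steady state
  if (is.null(p$deltaT) && preset == "serum") {
    p$deltaT <- .calibrate_deltaT(p)
  }
  if (is.null(p$deltaT) && preset == "steady") {
    # TDMD decay equal to basal decay at the resting target level, so that
    # removing the TDMD term doubles the steady-state miRNA level
    p$deltaT <- p$delta0 * (p$target + p$K) / p$target
  }
  stopifnot(!is.null(p$sigma), !is.null(p$delta0), !is.null(p$deltaT),
            !is.null(p$K), !is.null(p$M0), !is.null(p$target),
            p$sigma >= 0, p$delta0 >= 0, p$deltaT >= 0, p$K > 0, p$M0 >= 0)
  structure(p, class = "tdmd_params")
}

# deltaT such that the miRNA halves over the first 4 h of the target pulse
.calibrate_deltaT <- function(p) {
  ratio_at_4h <- function(dT) {
    q <- p
    q$deltaT <- dT
    class(q) <- "tdmd_params"
    tr <- simulate_tdmd_kinetics(q, dt = 0.05, t_end = 4)
    tr$M[nrow(tr)] / p$M0 - 0.5
  }
  stats::uniroot(ratio_at_4h, c(0, 5), tol = 1e-8)$root
}

#' Simulate miRNA levels under target-directed degradation
#'
#' Integrates `dM/dt = sigma - (delta0 + deltaT * T(t)/(T(t)+K)) * M` with
#' explicit fourth-order Runge-Kutta stepping (via [deSolve::ode()]) and
#' reports the instantaneous total decay rate and half-life alongside the
#' trajectory.
#'
#' @param params A [tdmd_params()] object.
#' @param dt Fixed integration step (h), at most 0.1.
#' @param t_end End of the simulated span (h).
#' @return data.frame with columns `time`, `M` (copies per cell),
#'   `decay_rate` (1/h) and `half_life` (h).
#' @export
simulate_tdmd_kinetics <- function(params, dt = 0.05, t_end = 24) {
  stopifnot(inherits(params, "tdmd_params"))
  if (dt > 0.1) stop("integration step dt must be at most 0.1 h")
  target_fn <- if (is.function(params$target)) params$target
               else function(t) rep_len(params$target, length(t))
  deriv <- function(t, y, parms) {
    rate <- params$delta0 +
      params$deltaT * target_fn(t) / (target_fn(t) + params$K)
    list(params$sigma - rate * y)
  }
  times <- seq(0, t_end, by = dt)
  sol <- deSolve::ode(y = c(M = params$M0), times = times, func = deriv,
                      parms = NULL, method = "rk4")
  M <- sol[, "M"]
  if (any(M < 0)) {
    stop("negative miRNA level during integration: step too large")
  }
  rate <- params$delta0 +
    params$deltaT * target_fn(times) / (target_fn(times) + params$K)
  data.frame(time = times, M = as.numeric(M), decay_rate = rate,
             half_life = log(2) / rate)
}

#' Default reference contexts for read simulation
#'
#' miR-30 family mature sequences paired with synthetic downstream genomic
#' contexts. The contexts are invented (chosen to start with G/C so that
#' templated extensions are distinguishable from A/U tails); they are not
#' the genomic sequences of the miR-30 loci.
#'
#' @return A [mirna_ref_context()] table.
#' @export
default_ref_contexts <- function() {
  fam <- read_fasta(tdmd_extdata("mir30_family_mature.fa"))
  mirna_ref_context(
    name = fam$id,
    canonical_seq = fam$seq,
    downstream_genomic = rep(c("GCGGCA", "CGCAGG", "GGCACG", "CCGTGG",
                               "GCCTGC"), length.out = nrow(fam)))
}

#' Generate synthetic small-RNA reads with planted isomiR classes
#'
#' Draws reads from the given references with the requested isomiR class
#' fractions: canonical reads, templated 3' extensions, non-templated A/U
#' and mixed tails, and 3' trimmed forms. The realised per-class counts
#' are returned as ground truth.
#'
#' @param refs A [mirna_ref_context()] table.
#' @param class_fractions Named fractions over the isomiR classes
#'   (CANONICAL, TEMPLATED_3P, NT_A, NT_U, NT_MIXED, TRIM); must sum to 1.
#' @param n_reads Number of reads.
#' @param seed RNG seed (bit-for-bit reproducible).
#' @param path Optional FASTQ output path.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame of planted class per read).
#' @export
gen_srna_reads <- function(refs,
                           class_fractions = c(CANONICAL = 0.60,
                                               TEMPLATED_3P = 0.05,
                                               NT_A = 0.15, NT_U = 0.07,
                                               NT_MIXED = 0.03, TRIM = 0.10),
                           n_reads = 1000L, seed = NULL, path = NULL) {
  stopifnot(abs(sum(class_fractions) - 1) < 1e-8)
  .with_seed(seed, {
    if (n_reads == 0) {
      reads <- data.frame(id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE)
      truth <- data.frame(id = character(0), mirna = character(0),
                          class = character(0), stringsAsFactors = FALSE)
    } else {
      ref_idx <- sample.int(nrow(refs), n_reads, replace = TRUE)
      cls <- sample(names(class_fractions), n_reads, replace = TRUE,
                    prob = class_fractions)
      seqs <- character(n_reads)
      for (i in seq_len(n_reads)) {
        can <- refs$canonical_seq[ref_idx[i]]
        down <- refs$downstream_genomic[ref_idx[i]]
        seqs[i] <- switch(cls[i],
          CANONICAL = can,
          TEMPLATED_3P = paste0(can, substr(down, 1, sample(1:2, 1))),
          NT_A = paste0(can, strrep("A", sample(1:3, 1))),
          NT_U = paste0(can, strrep("T", sample(1:3, 1))),
          NT_MIXED = paste0(can, sample(c("AT", "TA", "AAT", "TAA"), 1)),
          TRIM = substr(can, 1, nchar(can) - sample(1:3, 1)))
      }
      reads <- data.frame(id = sprintf("read%06d", seq_len(n_reads)),
                          seq = seqs, qual = strrep("I", nchar(seqs)),
                          stringsAsFactors = FALSE)
      truth <- data.frame(id = reads$id, mirna = refs$name[ref_idx],
                          class = cls, stringsAsFactors = FALSE)
    }
    if (!is.null(path)) {
      writeLines(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual),
                 path)
    }
    list(reads = reads, truth = truth)
  })
}

#' Generate synthetic two-channel flow-cytometry events
#'
#' Bivariate log-normal model of a bidirectional reporter: the co-reporter
#' (dNGFR) is log-normal; the sensor channel tracks it proportionally,
#' divided by the planted repression fold for the sensor population, with
#' multiplicative log-normal measurement noise.
#'
#' @param n Events per population.
#' @param repression_fold Planted fold (>= 1).
#' @param noise_sigma Measurement noise, natural-log units (default 0.3).
#' @param seed RNG seed.
#' @param ngfr_meanlog,ngfr_sdlog dNGFR log-normal parameters.
#' @return List with `sensor` and `control` data.frames (`dGFP`, `dNGFR`).
#' @export
gen_flow_events <- function(n, repression_fold, noise_sigma = 0.3,
                            seed = NULL, ngfr_meanlog = log(1000),
                            ngfr_sdlog = 1) {
  if (repression_fold < 1) stop("repression fold must be at least 1")
  .with_seed(seed, {
    pop <- function(fold) {
      ngfr <- stats::rlnorm(n, ngfr_meanlog, ngfr_sdlog)
      gfp <- ngfr / fold * exp(stats::rnorm(n, 0, noise_sigma))
      data.frame(dGFP = gfp, dNGFR = ngfr)
    }
    list(sensor = pop(repression_fold), control = pop(1))
  })
}

#' Generate synthetic qPCR standards
#'
#' A titration series on a known line `Cq = intercept + slope *
#' log10(copies)`, optionally with Gaussian Cq noise.
#'
#' @param copies Known copy numbers (default a 10-fold series over 6
#'   orders of magnitude).
#' @param slope,intercept Line parameters (default slope -3.3219, a 100%
#'   efficient assay).
#' @param noise_sd Gaussian noise on Cq (cycles).
#' @param seed RNG seed.
#' @param path Optional TSV output path.
#' @return data.frame with columns `known_copies`, `measured_Cq`.
#' @export
gen_standards <- function(copies = 10^(2:7), slope = -log2(10),
                          intercept = 40, noise_sd = 0, seed = NULL,
                          path = NULL) {
  .with_seed(seed, {
    cq <- intercept + slope * log10(copies) +
      stats::rnorm(length(copies), 0, noise_sd)
    out <- data.frame(known_copies = copies, measured_Cq = cq)
    if (!is.null(path)) {
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    out
  })
}
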