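#' Configuration of a regulatory phenotype simulation
#'
#' Defines the study conditions for one simulated cohort: sample size,
#' variant content and minor-allele-frequency spectrum, the regulatory
#' annotation layout, and the variance decomposition of the liability.
#'
#' The liability of individual i is
#' `eta_i = y_epi + y_direct + y_env + y_inter`, with the genetic
#' components rescaled exactly (population variance over the n individuals)
#' to `h2_epi`, `h2_direct` and `h2_inter`, and the environmental component
#' drawn `N(0, 1 - h2_epi - h2_direct - h2_inter)`. Binary labels come
#' either from thresholding the liability so that exactly `round(n *
#' prevalence)` individuals are cases (default), or from a Bernoulli draw
#' under a logit link with the intercept calibrated so the mean case
#' probability equals the prevalence.
#'
#' @param n Number of individuals.
#' @param n_blocks Number of LD blocks (one causal gene per block).
#' @param windows_per_block Extraction windows per block; together with
#'   `geometry` this fixes the block length.
#' @param geometry A [window_config()] giving the sequence geometry used
#'   when the cohort is realized as sequences (desk-scale default:
#'   4,096 bp input, 16 bins x 128 bp).
#' @param causal_per_gene Causal variants per causal gene (inside
#'   regulatory elements within 1 Mb of the gene).
#' @param m_direct Direct-effect SNVs per block (outside regulatory
#'   elements of causal genes).
#' @param m_neutral Neutral SNVs per block (no phenotype contribution).
#' @param h2_epi,h2_direct,h2_inter Liability variance proportions of the
#'   epigenetic, SNP-direct and SNP-interaction components (sum <= 1).
#' @param prevalence Sample prevalence lambda in (0, 1).
#' @param rare_fraction Fraction of phenotype-contributing sites (causal
#'   regulatory + direct) drawn with a rare minor allele frequency.
#' @param rare_range,common_range MAF ranges for rare and common sites
#'   (defaults `[0.001, 0.01)` and `[0.05, 0.5]`).
#' @param f_inter Fraction of causal regulatory sites entering disjoint
#'   multiplicative interaction pairs.
#' @param n_tf Number of transcription factors.
#' @param tf_hit_prob Per-TF probability that a causal site is a binding
#'   site (uncoupled binding matrix; ignored in sequence-coupled mode).
#' @param n_re Regulatory-element intervals per block.
#' @param ld_rho Optional latent-Gaussian haplotype correlation in
#'   `[0, 1)` (0 = independent sites). Sites within the same `ld_group_bp`
#'   stretch of a block share one latent factor per haplotype, giving the
#'   block a local, approximately low-rank LD structure.
#' @param ld_group_bp Width in bp of one LD factor group (used when
#'   `ld_rho > 0`).
#' @param phenotype_mode `"threshold"` (default) or `"bernoulli"`.
#' @param seed Master seed; every stochastic step consumes a named child
#'   seed derived from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n = 4000L, n_blocks = 1L, windows_per_block = 2L,
                       geometry = window_config(4096L, 16L, 128L),
                       causal_per_gene = 100L, m_direct = 100L, m_neutral = 100L,
                       h2_epi = 0.5, h2_direct = 0.3, h2_inter = 0.1,
                       prevalence = 0.5, rare_fraction = 0,
                       rare_range = c(0.001, 0.01), common_range = c(0.05, 0.5),
                       f_inter = 0.5, n_tf = 10L, tf_hit_prob = 0.3,
                       n_re = 8L, ld_rho = 0, ld_group_bp = 512L,
                       phenotype_mode = c("threshold", "bernoulli"),
                       seed = 1L) {
  phenotype_mode <- match.arg(phenotype_mode)
  h2 <- c(h2_epi, h2_direct, h2_inter)
  if (any(h2 < 0) || any(h2 > 1) || sum(h2) > 1 + 1e-12)
    stop_epiprs("variance proportions must lie in [0,1] and sum to at most 1 (sum=%.3f)", sum(h2))
  if (prevalence <= 0 || prevalence >= 1)
    stop_epiprs("prevalence must lie strictly between 0 and 1")
  if (rare_fraction < 0 || rare_fraction > 1)
    stop_epiprs("rare_fraction must lie in [0,1]")
  if (rare_range[2] > common_range[1] || rare_range[1] <= 0 || common_range[2] > 0.5)
    stop_epiprs("MAF ranges must be disjoint and within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop_epiprs("ld_rho must lie in [0, 1)")
  structure(
    list(n = as.integer(n), n_blocks = as.integer(n_blocks),
         windows_per_block = as.integer(windows_per_block), geometry = geometry,
         causal_per_gene = as.integer(causal_per_gene),
         m_direct = as.integer(m_direct), m_neutral = as.integer(m_neutral),
         h2_epi = h2_epi, h2_direct = h2_direct, h2_inter = h2_inter,
         prevalence = prevalence, rare_fraction = rare_fraction,
         rare_range = rare_range, common_range = common_range,
         f_inter = f_inter, n_tf = as.integer(n_tf), tf_hit_prob = tf_hit_prob,
         n_re = as.integer(n_re), ld_rho = ld_rho,
         ld_group_bp = as.integer(ld_group_bp),
         phenotype_mode = phenotype_mode, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: n=%d, %d block(s) x %d window(s), %d causal + %d direct + %d neutral sites/block\n",
    "  h2: epi=%.2f direct=%.2f inter=%.2f (env=%.2f); prevalence=%.2f; rare fraction=%.2f; mode=%s; seed=%d\n"),
    x$n, x$n_blocks, x$windows_per_block, x$causal_per_gene, x$m_direct, x$m_neutral,
    x$h2_epi, x$h2_direct, x$h2_inter, 1 - x$h2_epi - x$h2_direct - x$h2_inter,
    x$prevalence, x$rare_fraction, x$phenotype_mode, x$seed))
  invisible(x)
}

# Sample `count` positions from the union of intervals (0-based half-open),
# pairwise separated by at least `spacing` bp. Deterministic under the
# current RNG state.
sample_spaced_positions <- function(intervals, count, spacing, forbidden = integer(0)) {
  cand <- unlist(lapply(seq_len(nrow(intervals)), function(i)
    seq.int(intervals$start[i], intervals$end[i] - 1L)))
  cand <- setdiff(cand, unlist(lapply(forbidden, function(p) (p - spacing):(p + spacing))))
  chosen <- integer(0)
  cand <- sample(cand)
  for (p in cand) {
    if (length(chosen) == count) break
    if (all(abs(chosen - p) > spacing)) chosen <- c(chosen, p)
  }
  if (length(chosen) < count)
    stop_epiprs("could not place %d sites with %d bp spacing (placed %d); enlarge the block or REs",
                count, spacing, length(chosen))
  sort(chosen)
}

#' Simulate a phased synthetic cohort
#'
#' Generates block layouts, reference sequences, SNV positions with
#' rare/common MAF assignment, and phased haplotypes (each allele an
#' independent Bernoulli draw at the site's MAF; optionally correlated
#' within a block through a latent Gaussian with correlation `ld_rho`).
#' Monomorphic sites are redrawn. When an extractor is supplied
#' (sequence-coupled mode), causal regulatory sites are planted inside that
#' extractor's motif instances so that the alternate allele genuinely
#' disrupts a motif — closing the loop genotype -> sequence -> feature ->
#' phenotype.
#'
#' @param cfg A [sim_config()].
#' @param extractor Optional `seq_extractor` for sequence-coupled mode; its
#'   geometry must equal `cfg$geometry`.
#' @return An object of class `regpheno_cohort`: `samples`, `sites`
#'   (data.frame: `id`, `chrom`, `pos` 1-based, `pos0`, `ref`, `alt`,
#'   `maf`, `role` in {re_causal, direct, neutral}, `block`, `tf`),
#'   `H1`/`H2` (n x m phased allele matrices), `blocks`, `re_intervals`,
#'   `references` (named contig sequences), `coupled`, `cfg`.
#' @export
simulate_cohort <- function(cfg, extractor = NULL) {
  coupled <- !is.null(extractor)
  if (coupled && !identical(extractor$cfg[c("input_length", "n_bins", "bin_size")],
                            cfg$geometry[c("input_length", "n_bins", "bin_size")]))
    stop_epiprs("extractor geometry does not match the simulation geometry")
  geom <- cfg$geometry
  span <- cfg$windows_per_block * geom$central_length
  margin <- geom$margin
  contig_len <- span + 2L * margin
  samples <- sprintf("S%04d", seq_len(cfg$n))
  bases <- c("A", "C", "G", "T")
  motif_len <- if (coupled) extractor$motif_length else 0L
  spacing_causal <- max(4L, motif_len + 2L)

  blocks <- data.frame(id = sprintf("block_%d", seq_len(cfg$n_blocks)),
                       chrom = sprintf("chrSim%d", seq_len(cfg$n_blocks)),
                       start = margin, end = margin + span,
                       stringsAsFactors = FALSE)

  references <- character(cfg$n_blocks); names(references) <- blocks$chrom
  sites_list <- list(); re_list <- list()
  for (b in seq_len(cfg$n_blocks)) {
    set.seed(child_seed(cfg$seed, paste0("layout", b)))
    ref <- sample(bases, contig_len, replace = TRUE)
    # regulatory elements: n_re intervals in the block
    re_len <- max(spacing_causal * 4L, span %/% (2L * cfg$n_re))
    gap <- (span - cfg$n_re * re_len) %/% (cfg$n_re + 1L)
    if (gap < 0) stop_epiprs("block too short for %d regulatory elements", cfg$n_re)
    re_start <- blocks$start[b] + gap + (seq_len(cfg$n_re) - 1L) * (re_len + gap)
    res <- data.frame(block = blocks$id[b], chrom = blocks$chrom[b],
                      start = re_start, end = re_start + re_len,
                      stringsAsFactors = FALSE)
    # keep planted motifs clear of the contig edge
    res$start <- pmax(res$start, blocks$start[b] + motif_len + 1L)
    causal_pos <- sample_spaced_positions(res, cfg$causal_per_gene, spacing_causal)
    nonre <- data.frame(start = c(blocks$start[b], res$end),
                        end = c(res$start, blocks$end[b]))
    nonre <- nonre[nonre$end > nonre$start, , drop = FALSE]
    direct_pos <- sample_spaced_positions(nonre, cfg$m_direct, 1L)
    neutral_pos <- if (cfg$m_neutral > 0)
      sample_spaced_positions(nonre, cfg$m_neutral, 0L, forbidden = direct_pos)
    else integer(0)
    pos0 <- c(causal_pos, direct_pos, neutral_pos)
    role <- c(rep("re_causal", length(causal_pos)),
              rep("direct", length(direct_pos)),
              rep("neutral", length(neutral_pos)))
    tf <- rep(NA_integer_, length(pos0))
    if (coupled) {
      # plant a motif instance across each causal site; the reference
      # carries the consensus, the alternate allele destroys it
      tf[role == "re_causal"] <- rep_len(seq_len(cfg$n_tf), length(causal_pos))
      for (ci in seq_along(causal_pos)) {
        t_i <- tf[ci]
        motif <- extractor$motifs[((t_i - 1L) %% length(extractor$motifs)) + 1L]
        off <- sample.int(motif_len, 1L) - 1L
        at <- causal_pos[ci] - off  # 0-based start of the planted instance
        ref[(at + 1L):(at + motif_len)] <- strsplit(motif, "")[[1]]
      }
    }
    refbase <- ref[pos0 + 1L]
    alt <- vapply(refbase, function(rb) sample(setdiff(bases, rb), 1L), "")
    ord <- order(pos0)
    sites_list[[b]] <- data.frame(
      id = sprintf("%s_v%d", blocks$id[b], seq_along(pos0)),
      chrom = blocks$chrom[b], pos = pos0[ord] + 1L, pos0 = pos0[ord],
      ref = refbase[ord], alt = alt[ord], role = role[ord],
      block = blocks$id[b], tf = tf[ord], stringsAsFactors = FALSE
    )
    re_list[[b]] <- res
    references[b] <- paste(ref, collapse = "")
  }
  sites <- do.call(rbind, sites_list)
  rownames(sites) <- NULL
  re_intervals <- do.call(rbind, re_list)

  # MAF assignment: contributing sites (re_causal + direct) get the
  # rare/common mix; neutral sites are common
  set.seed(child_seed(cfg$seed, "maf"))
  m <- nrow(sites)
  maf <- numeric(m)
  for (r in c("re_causal", "direct")) {
    idx <- which(sites$role == r)
    n_rare <- round(cfg$rare_fraction * length(idx))
    rare_idx <- if (n_rare > 0) sample(idx, n_rare) else integer(0)
    common_idx <- setdiff(idx, rare_idx)
    maf[rare_idx] <- runif(length(rare_idx), cfg$rare_range[1], cfg$rare_range[2])
    maf[common_idx] <- runif(length(common_idx), cfg$common_range[1], cfg$common_range[2])
  }
  idx <- which(sites$role == "neutral")
  maf[idx] <- runif(length(idx), cfg$common_range[1], cfg$common_range[2])
  sites$maf <- maf

  # phased haplotypes; with ld_rho > 0 sites within one ld_group_bp stretch
  # share a latent factor per haplotype (local low-rank LD)
  set.seed(child_seed(cfg$seed, "haplotypes"))
  n <- cfg$n
  draw_alleles <- function(p, rho, z) {
    if (rho > 0) {
      e <- rnorm(n)
      u <- pnorm(sqrt(rho) * z + sqrt(1 - rho) * e)
      as.integer(u < p)
    } else {
      as.integer(runif(n) < p)
    }
  }
  group <- interaction(sites$block, sites$pos0 %/% cfg$ld_group_bp, drop = TRUE)
  G <- nlevels(group)
  H1 <- matrix(0L, n, m); H2 <- matrix(0L, n, m)
  z1 <- if (cfg$ld_rho > 0) matrix(rnorm(n * G), n, G) else NULL
  z2 <- if (cfg$ld_rho > 0) matrix(rnorm(n * G), n, G) else NULL
  for (k in seq_len(m)) {
    g <- as.integer(group[k])
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      a1 <- draw_alleles(maf[k], cfg$ld_rho, z1[, g])
      a2 <- draw_alleles(maf[k], cfg$ld_rho, z2[, g])
      if (sum(a1) + sum(a2) > 0L && sum(a1) + sum(a2) < 2L * n) { ok <- TRUE; break }
    }
    if (!ok)
      stop_epiprs("site %s (MAF %.4g) stayed monomorphic after 100 redraws; increase n",
                  sites$id[k], maf[k])
    H1[, k] <- a1; H2[, k] <- a2
  }
  dimnames(H1) <- dimnames(H2) <- list(samples, sites$id)

  structure(
    list(samples = samples, sites = sites, H1 = H1, H2 = H2, blocks = blocks,
         re_intervals = re_intervals, references = references,
         coupled = coupled, cfg = cfg),
    class = "regpheno_cohort"
  )
}

#' @export
print.regpheno_cohort <- function(x, ...) {
  cat(sprintf("regpheno_cohort: %d samples x %d phased SNVs in %d block(s)%s\n",
              length(x$samples), nrow(x$sites), nrow(x$blocks),
              if (x$coupled) " (sequence-coupled)" else ""))
  invisible(x)
}

#' Diploid dosage matrix of a cohort
#' @param cohort A `regpheno_cohort`.
#' @return Integer matrix (samples x sites) in {0, 1, 2}.
#' @export
dosage_matrix <- function(cohort) cohort$H1 + cohort$H2

#' Normalize genotypes per site
#'
#' Standardizes each dosage column to mean 0 and (population) variance 1.
#'
#' @param cohort A `regpheno_cohort` or a dosage matrix.
#' @return Numeric matrix of normalized genotypes (samples x sites).
#' @export
normalize_genotypes <- function(cohort) {
  d <- if (inherits(cohort, "regpheno_cohort")) dosage_matrix(cohort) else as.matrix(cohort)
  mu <- colMeans(d)
  v <- colMeans(d^2) - mu^2
  if (any(v <= 0))
    stop_epiprs("monomorphic site(s) cannot be normalized: %s",
                paste(head(colnames(d)[v <= 0], 3), collapse = ", "))
  sweep(sweep(d, 2, mu), 2, sqrt(v), "/")
}

#' Build the annotation set of a simulated cohort
#'
#' Places one causal gene per block (at a random in-block anchor),
#' records the regulatory-element intervals (all within 1 Mb of the
#' anchor), the per-gene causal-variant sets, and the binary TF-binding
#' matrix. In sequence-coupled cohorts the binding matrix is read off the
#' planted motif assignment; otherwise entries for causal sites are
#' Bernoulli(`tf_hit_prob`) draws, with each TF guaranteed at least one
#' binding site among the causal variants.
#'
#' @param cohort A `regpheno_cohort`.
#' @param cfg The `sim_config` (defaults to the cohort's).
#' @return An object of class `annotation_set`: `genes` (data.frame: gene
#'   id, block, chrom, anchor), `causal_sets` (named list of site-index
#'   vectors per gene), `tf` (TF ids), `B` (n_tf x m binary matrix),
#'   `re_intervals`.
#' @export
build_annotations <- function(cohort, cfg = cohort$cfg) {
  sites <- cohort$sites
  set.seed(child_seed(cfg$seed, "annotations"))
  genes <- data.frame(
    gene = sprintf("gene_%d", seq_len(nrow(cohort$blocks))),
    block = cohort$blocks$id, chrom = cohort$blocks$chrom,
    anchor = cohort$blocks$start +
      vapply(cohort$blocks$end - cohort$blocks$start,
             function(len) sample.int(len, 1L), 1L),
    stringsAsFactors = FALSE
  )
  causal_sets <- list()
  for (g in seq_len(nrow(genes))) {
    idx <- which(sites$block == genes$block[g] & sites$role == "re_causal")
    causal_sets[[genes$gene[g]]] <- idx
  }
  m <- nrow(sites)
  tf <- sprintf("TF%02d", seq_len(cfg$n_tf))
  B <- matrix(0L, cfg$n_tf, m, dimnames = list(tf, sites$id))
  causal_all <- which(sites$role == "re_causal")
  if (cohort$coupled) {
    for (k in causal_all) B[sites$tf[k], k] <- 1L
  } else {
    for (t_i in seq_len(cfg$n_tf)) {
      repeat {
        row <- rbinom(length(causal_all), 1L, cfg$tf_hit_prob)
        if (sum(row) >= 1L) break
      }
      B[t_i, causal_all] <- row
    }
  }
  structure(
    list(genes = genes, causal_sets = causal_sets, tf = tf, B = B,
         re_intervals = cohort$re_intervals),
    class = "annotation_set"
  )
}

#' Draw the random effects of the liability model
#'
#' Per-TF variances are inverse-gamma IG(shape 3, scale 1); the
#' regulatory effects `e_gtk ~ N(0, sigma_t^2)` are drawn for every
#' (gene, TF, causal variant) with a binding hit; direct effects
#' `beta_k ~ N(0,1)`; interaction pairs are disjoint random pairs of
#' causal sites with `gamma ~ N(0,1)` coefficients.
#'
#' @param annotations An `annotation_set`.
#' @param cohort The `regpheno_cohort`.
#' @param cfg The `sim_config` (defaults to the cohort's).
#' @return An object of class `effect_draws`: `sigma2_tf`, `w_causal`
#'   (per-site summed regulatory weight, length m), `beta` (per-site direct
#'   weight), `pairs` (2-column matrix of site indices), `gamma`.
#' @export
draw_effects <- function(annotations, cohort, cfg = cohort$cfg) {
  sites <- cohort$sites
  m <- nrow(sites)
  set.seed(child_seed(cfg$seed, "effects"))
  sigma2 <- 1 / rgamma(cfg$n_tf, shape = 3, rate = 1)  # IG(3, 1), mean 1/2
  w <- numeric(m)
  for (g in names(annotations$causal_sets)) {
    for (k in annotations$causal_sets[[g]]) {
      hits <- which(annotations$B[, k] == 1L)
      for (t_i in hits) w[k] <- w[k] + rnorm(1, 0, sqrt(sigma2[t_i]))
    }
  }
  beta <- numeric(m)
  direct_idx <- which(sites$role == "direct")
  beta[direct_idx] <- rnorm(length(direct_idx))
  causal_all <- which(sites$role == "re_causal")
  n_pairs <- round(cfg$f_inter * length(causal_all) / 2)
  pairs <- matrix(integer(0), 0, 2)
  gamma <- numeric(0)
  if (n_pairs > 0) {
    picked <- sample(causal_all, 2L * n_pairs)
    pairs <- matrix(picked, ncol = 2)
    gamma <- rnorm(n_pairs)
  }
  structure(list(sigma2_tf = sigma2, w_causal = w, beta = beta,
                 pairs = pairs, gamma = gamma),
            class = "effect_draws")
}

# Rescale a raw component to population mean 0 and variance h2 exactly.
rescale_component <- function(raw, h2, label) {
  n <- length(raw)
  if (h2 == 0) return(numeric(n))
  v <- pop_var(raw)
  if (v <= 0)
    stop_epiprs("raw %s component is constant but its target variance is %.3g (degenerate draw)",
                label, h2)
  (raw - mean(raw)) * sqrt(h2 / v)
}

#' Compute the four liability components
#'
#' The epigenetic component is the triple sum over causal genes, TFs and
#' causal variants of `X_ik * B_tk * e_gtk`; the direct component sums
#' `X_ik * beta_k` over non-regulatory SNVs; the interaction component sums
#' `gamma * X_ip * X_iq` over the drawn disjoint pairs. Each genetic
#' component is affinely rescaled to population mean 0 and exactly its
#' target variance; the environmental component is drawn
#' `N(0, 1 - h2_epi - h2_direct - h2_inter)`.
#'
#' @param X Normalized genotype matrix from [normalize_genotypes()].
#' @param annotations An `annotation_set`.
#' @param draws An `effect_draws`.
#' @param cfg The `sim_config`.
#' @return An object of class `liability_components`: `y_epi`, `y_direct`,
#'   `y_env`, `y_inter`, `liability` (their sum), and the echoed target
#'   variances.
#' @export
compute_liability <- function(X, annotations, draws, cfg) {
  n <- nrow(X)
  y_epi <- if (cfg$h2_epi > 0)
    rescale_component(as.vector(X %*% draws$w_causal), cfg$h2_epi, "epigenetic")
  else numeric(n)
  y_direct <- if (cfg$h2_direct > 0)
    rescale_component(as.vector(X %*% draws$beta), cfg$h2_direct, "direct")
  else numeric(n)
  y_inter <- numeric(n)
  if (cfg$h2_inter > 0) {
    if (nrow(draws$pairs) == 0)
      stop_epiprs("h2_inter > 0 but no interaction pairs were drawn (f_inter too small?)")
    raw <- numeric(n)
    for (j in seq_len(nrow(draws$pairs)))
      raw <- raw + draws$gamma[j] * X[, draws$pairs[j, 1]] * X[, draws$pairs[j, 2]]
    y_inter <- rescale_component(raw, cfg$h2_inter, "interaction")
  }
  v_env <- 1 - cfg$h2_epi - cfg$h2_direct - cfg$h2_inter
  set.seed(child_seed(cfg$seed, "environment"))
  y_env <- if (v_env > 0) rnorm(n, 0, sqrt(v_env)) else numeric(n)
  structure(
    list(y_epi = y_epi, y_direct = y_direct, y_env = y_env, y_inter = y_inter,
         liability = y_epi + y_direct + y_env + y_inter,
         h2 = c(epi = cfg$h2_epi, direct = cfg$h2_direct, inter = cfg$h2_inter,
                env = v_env)),
    class = "liability_components"
  )
}

#' Assign case/control labels from liabilities
#'
#' Threshold mode (default): the `round(n * prevalence)` largest
#' liabilities become cases (ties broken by a seeded random order); the
#' reported intercept `alpha0` is minus the implied liability cut, so
#' `alpha0 + eta_i >= 0` iff case. Bernoulli mode: `alpha0` is found by
#' monotone root-finding so the mean of `plogis(alpha0 + eta_i)` equals the
#' prevalence within 1e-8, then labels are Bernoulli draws at those
#' probabilities.
#'
#' @param components A `liability_components`.
#' @param cfg The `sim_config`.
#' @return A list with `labels` (0/1 integer vector), `alpha0`, and `mu`
#'   (case probabilities; in threshold mode the 0/1 indicator).
#' @export
assign_phenotypes <- function(components, cfg) {
  eta <- components$liability
  if (!all(is.finite(eta))) stop_epiprs("non-finite liabilities")
  n <- length(eta)
  set.seed(child_seed(cfg$seed, "phenotypes"))
  if (cfg$phenotype_mode == "threshold") {
    k <- round(n * cfg$prevalence)
    tie_break <- runif(n)
    ord <- order(-eta, tie_break)
    labels <- integer(n)
    labels[ord[seq_len(k)]] <- 1L
    cut <- if (k >= 1 && k < n) (eta[ord[k]] + eta[ord[k + 1]]) / 2 else if (k >= 1) eta[ord[k]] else max(eta) + 1
    list(labels = labels, alpha0 = -cut, mu = as.numeric(labels))
  } else {
    f <- function(a0) mean(plogis(a0 + eta)) - cfg$prevalence
    lo <- qlogis(cfg$prevalence) - max(eta)
    hi <- qlogis(cfg$prevalence) - min(eta)
    if (hi - lo < 1e-12) {
      # all liabilities equal: the root equation has the closed form
      a0 <- qlogis(cfg$prevalence) - eta[1]
      mu <- plogis(a0 + eta)
      return(list(labels = rbinom(n, 1L, mu), alpha0 = a0, mu = mu))
    }
    root <- tryCatch(
      uniroot(f, c(lo, hi), tol = 1e-12, maxiter = 200L),
      error = function(e)
        stop_epiprs("intercept root-finding failed on [%.3g, %.3g]: %s", lo, hi, conditionMessage(e)))
    a0 <- root$root
    mu <- plogis(a0 + eta)
    list(labels = rbinom(n, 1L, mu), alpha0 = a0, mu = mu)
  }
}

#' Run the full regulatory phenotype simulation
#'
#' Chains [simulate_cohort()], [build_annotations()], [draw_effects()],
#' [normalize_genotypes()], [compute_liability()] and
#' [assign_phenotypes()].
#'
#' @param cfg A [sim_config()].
#' @param extractor Optional `seq_extractor` for sequence-coupled mode.
#' @return An object of class `regpheno_sim`: `cohort`, `annotations`,
#'   `draws`, `components`, `labels`, `alpha0`, `mu`, `cfg`.
#' @export
regpheno <- function(cfg = sim_config(), extractor = NULL) {
  cohort <- simulate_cohort(cfg, extractor)
  annotations <- build_annotations(cohort, cfg)
  draws <- draw_effects(annotations, cohort, cfg)
  X <- normalize_genotypes(cohort)
  components <- compute_liability(X, annotations, draws, cfg)
  ph <- assign_phenotypes(components, cfg)
  structure(
    list(cohort = cohort, annotations = annotations, draws = draws,
         components = components, labels = ph$labels, alpha0 = ph$alpha0,
         mu = ph$mu, cfg = cfg),
    class = "regpheno_sim"
  )
}

#' @export
print.regpheno_sim <- function(x, ...) {
  print(x$cohort)
  cat(sprintf("  %d cases / %d controls (alpha0 = %.4f, mode = %s)\n",
              sum(x$labels == 1), sum(x$labels == 0), x$alpha0, x$cfg$phenotype_mode))
  cat(sprintf("  realized component variances: epi=%.4f direct=%.4f inter=%.4f env=%.4f\n",
              pop_var(x$components$y_epi), pop_var(x$components$y_direct),
              pop_var(x$components$y_inter), pop_var(x$components$y_env)))
  invisible(x)
}

#' Run a grid of simulation settings with replicates
#'
#' For every setting and replicate a fresh child seed is derived
#' deterministically from the master seed, the setting is evaluated by
#' `fun`, and the returned rows are collected into one tidy table.
#'
#' @param settings A named list of `sim_config` objects (or of argument
#'   lists passed to [sim_config()]).
#' @param n_reps Replicates per setting.
#' @param fun Function `(cfg, setting_name, replicate)` returning a
#'   data.frame of result rows.
#' @param master_seed Master seed for the replicate-seed derivation.
#' @return A data.frame with `setting`, `replicate`, `seed` and the columns
#'   returned by `fun`.
#' @export
run_replicates <- function(settings, n_reps, fun, master_seed = 1L) {
  if (n_reps < 1) stop_epiprs("n_reps must be >= 1")
  rows <- list()
  for (s in names(settings)) {
    base <- settings[[s]]
    if (!inherits(base, "sim_config")) base <- do.call(sim_config, base)
    for (r in seq_len(n_reps)) {
      seed_sr <- child_seed(master_seed, paste0(s, "::rep", r))
      cfg <- base; cfg$seed <- seed_sr
      res <- fun(cfg, s, r)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(setting = s, replicate = r, seed = seed_sr), res)
    }
  }
  do.call(rbind, rows)
}
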