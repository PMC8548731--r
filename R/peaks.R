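#' Conditional binomial window enrichment test
#'
#' Under the null of equal IP and input rates, the IP count conditioned on
#' the window total is Binomial(n = x_ip + x_in, p0 = N_ip / (N_ip + N_in)).
#' Returns the one-sided upper tail P(X >= x_ip); windows with zero total
#' get p = 1. Vectorised over counts.
#'
#' @param x_ip,x_in Window counts in the IP and input fraction.
#' @param N_ip,N_in Library totals.
#' @return One-sided p-values.
#' @export
window_test <- function(x_ip, x_in, N_ip, N_in) {
  if (any(c(x_ip, x_in) < 0)) stop("negative counts")
  stopifnot(N_ip > 0, N_in > 0)
  n <- x_ip + x_in
  p0 <- N_ip / (N_ip + N_in)
  p <- pbinom(x_ip - 1, n, p0, lower.tail = FALSE)
  p[n == 0] <- 1
  p
}

# m6a level over a peak span: log2 of the (pseudocounted) IP rate over the
# input rate
m6a_level <- function(x_ip, x_in, N_ip, N_in) {
  log2(((x_ip + 1) / N_ip) / ((x_in + 1) / N_in))
}

# Recalibration of one-sided window p-values for count overdispersion.
# The conditional binomial has variance n*p0*q0, but NB counts give the
# IP-vs-total proportion variance (1 + 2*(alpha/r)*n*p0*q0) times that, so
# each window's implied z is deflated by that model factor; a robust global
# recentre/rescale (median/MAD) then absorbs residual miscalibration.
# Identity when alpha = 0 and the window set is too small for the robust
# step.
calibrate_pvalues <- function(p, n, p0, alpha, nrep, min_windows = 200L) {
  z <- qnorm(p, lower.tail = FALSE)
  f <- sqrt(1 + 2 * (alpha / nrep) * n * p0 * (1 - p0))
  z2 <- z / f
  ok <- is.finite(z2)
  if (sum(ok) >= min_windows) {
    s <- mad(z2[ok])
    if (s > 0) z2[ok] <- (z2[ok] - median(z2[ok])) / s
  }
  p2 <- pnorm(z2, lower.tail = FALSE)
  p2[!ok & p >= 1] <- 1
  p2[!ok & p <= 0] <- 0
  p2
}

# pooled method-of-moments NB dispersion across windows, estimated per
# condition x assay replicate group on depth-normalized counts
estimate_window_dispersion <- function(wcm) {
  libs <- wcm$libs
  ests <- c()
  for (cond in unique(libs$condition)) for (a in c("ip", "input")) {
    cols <- libs$lib_id[libs$condition == cond & libs$assay == a]
    if (length(cols) < 2L) next
    m <- wcm$counts[, cols, drop = FALSE]
    tot <- colSums(m)
    m <- sweep(m, 2, tot / mean(tot), "/")
    mu <- rowMeans(m)
    v <- apply(m, 1, var)
    keep <- mu > 1
    if (sum(keep) < 50L) next
    ests <- c(ests, max(sum(v[keep] - mu[keep]) / sum(mu[keep]^2), 0))
  }
  if (!length(ests)) 0 else mean(ests)
}

# library totals and replicate-summed window counts for one condition
condition_counts <- function(wcm, condition) {
  libs <- wcm$libs
  ip_cols <- libs$lib_id[libs$condition == condition & libs$assay == "ip"]
  in_cols <- libs$lib_id[libs$condition == condition & libs$assay == "input"]
  if (!length(ip_cols)) stop("no IP libraries for condition ", condition)
  list(x_ip = rowSums(wcm$counts[, ip_cols, drop = FALSE]),
       x_in = rowSums(wcm$counts[, in_cols, drop = FALSE]),
       N_ip = sum(wcm$counts[, ip_cols]),
       N_in = sum(wcm$counts[, in_cols]))
}

# indices of a non-overlapping subset of a gene's windows quantifying the
# span [a, b): only windows fully inside the span, strided by one width
# from its start, so flanking windows cannot dilute the enrichment estimate
disjoint_windows <- function(win, gene_id, a, b, width) {
  idx <- which(win$gene_id == gene_id & win$s_start >= a & win$s_end <= b)
  if (!length(idx)) {   # span narrower than one window: nearest overlap
    idx <- which(win$gene_id == gene_id & win$s_start < b & win$s_end > a)
    return(utils::head(idx, 1L))
  }
  sel <- seq(a, b - 1, by = width)
  idx[win$s_start[idx] %in% sel]
}

#' Call m6A peaks from windowed IP/input counts
#'
#' Replicate counts are summed per window, each window is tested with
#' [window_test()], Benjamini-Hochberg adjustment is applied across all
#' windows of the condition, and windows passing `q_threshold` are merged
#' within a gene when their spliced gap is at most one window step. A merged
#' peak inherits the minimum window p (and that window's q); its summit is
#' the mid-point of its maximally enriched window.
#'
#' @param wcm A [window_counts()].
#' @param condition Condition label to call peaks in.
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @param calibrate Recalibrate window p-values for count overdispersion
#'   before BH (robust z recentring/rescaling; default `TRUE`).
#' @return data.frame with one row per peak: genomic interval, host gene,
#'   summit, `m6a_level`, `p`, `fdr`, `n_windows`.
#' @export
call_peaks <- function(wcm, condition, q_threshold = 0.05, calibrate = TRUE) {
  win <- wcm$windows
  width <- attr(win, "width")
  step <- attr(win, "step")
  if (!nrow(win))
    return(empty_peaks())
  cc <- condition_counts(wcm, condition)
  p <- window_test(cc$x_ip, cc$x_in, cc$N_ip, cc$N_in)
  if (calibrate) {
    alpha_hat <- estimate_window_dispersion(wcm)
    nrep <- sum(wcm$libs$condition == condition & wcm$libs$assay == "ip")
    p <- calibrate_pvalues(p, n = cc$x_ip + cc$x_in,
                           p0 = cc$N_ip / (cc$N_ip + cc$N_in),
                           alpha = alpha_hat, nrep = nrep)
  }
  q <- p.adjust(p, "BH")
  sig <- which(q <= q_threshold)
  stage_log("call_peaks", "%s: %d/%d windows significant at q <= %g",
            condition, length(sig), nrow(win), q_threshold)
  if (!length(sig)) return(empty_peaks())

  enrich <- ((cc$x_ip + 1) / cc$N_ip) / ((cc$x_in + 1) / cc$N_in)
  peaks <- list()
  for (gid in unique(win$gene_id[sig])) {
    idx <- sig[win$gene_id[sig] == gid]
    idx <- idx[order(win$s_start[idx])]
    # new peak when the spliced gap to the previous window exceeds one step
    grp <- cumsum(c(1L, tail(win$s_start[idx], -1) -
                        head(win$s_end[idx], -1) > step))
    for (gmem in split(idx, grp)) {
      a <- min(win$s_start[gmem]); b <- max(win$s_end[gmem])
      dj <- disjoint_windows(win, gid, a, b, width)
      x_ip <- sum(cc$x_ip[dj]); x_in <- sum(cc$x_in[dj])
      best <- gmem[which.min(p[gmem])]
      top <- gmem[which.max(enrich[gmem])]
      ex <- tx_exons_cache(wcm, win$transcript_id[top])
      # summit: enrichment-weighted centroid of the member windows -- robust
      # for flat-topped peaks, equals the max window for sharply peaked ones
      smid <- round(sum(((win$s_start[gmem] + win$s_end[gmem]) / 2) *
                          enrich[gmem]) / sum(enrich[gmem]))
      smid <- min(max(smid, 0L), sum(ex$end - ex$start) - 1L)
      summit <- t2g_exons(ex, win$strand[top], smid)
      peaks[[length(peaks) + 1L]] <- data.frame(
        gene_id = gid, chrom = win$chrom[top], strand = win$strand[top],
        start = min(win$g_start[gmem]), end = max(win$g_end[gmem]),
        s_start = a, s_end = b, summit = summit,
        m6a_level = m6a_level(x_ip, x_in, cc$N_ip, cc$N_in),
        p = p[best], fdr = q[best], n_windows = length(gmem),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, peaks)
  out[order(out$chrom, out$start), , drop = FALSE]
}

empty_peaks <- function() {
  data.frame(gene_id = character(), chrom = character(), strand = character(),
             start = integer(), end = integer(), s_start = integer(),
             s_end = integer(), summit = integer(), m6a_level = numeric(),
             p = numeric(), fdr = numeric(), n_windows = integer(),
             stringsAsFactors = FALSE)
}

# exon lookup bound to the annotation attached to a window set, if any;
# falls back to reconstructing a single pseudo-exon from the window table
tx_exons_cache <- function(wcm, transcript_id) {
  ann <- attr(wcm$windows, "annotation")
  if (!is.null(ann)) return(tx_exons(ann, transcript_id))
  w <- wcm$windows[wcm$windows$transcript_id == transcript_id, ]
  data.frame(transcript_id = transcript_id, chrom = w$chrom[1],
             start = min(w$g_start), end = max(w$g_end),
             strand = w$strand[1], stringsAsFactors = FALSE)
}

#' Differential methylation over the union peak set
#'
#' Peaks called in either condition are merged per gene (overlapping spliced
#' intervals unioned); for each merged peak a 2x2 table of replicate-summed
#' IP/input counts by condition is tested with a two-sided Fisher exact
#' test, BH-adjusted across peaks. `diff_log2_fc` is the D4 minus GM
#' difference of pseudocounted m6A levels and `diff_lg_fdr` is log10 of the
#' adjusted q.
#'
#' Two-sided Fisher exact test of one differential-methylation 2x2 table
#'
#' Cells: IP and input counts in the first condition (first row) and in the
#' second (second row). Two-sided by the sum-of-smaller-probability-tables
#' convention.
#'
#' @param x11,x12 IP and input counts, first condition.
#' @param x21,x22 IP and input counts, second condition.
#' @return The two-sided p-value.
#' @export
diff_peak_test <- function(x11, x12, x21, x22) {
  fisher.test(matrix(c(x11, x12, x21, x22), 2, byrow = TRUE))$p.value
}

#' @param peaks_gm,peaks_d4 Per-condition [call_peaks()] results.
#' @param wcm The [window_counts()] both conditions were called from.
#' @param q_threshold Threshold on the BH-adjusted differential q used only
#'   to label `status` (`hyper`/`hypo`/`ns`).
#' @return data.frame with the merged peak coordinates, per-condition m6A
#'   levels, `diff_log2_fc`, `pvalue`, `diff_fdr`, `diff_lg_fdr`, `status`.
#' @export
differential_peaks <- function(peaks_gm, peaks_d4, wcm, q_threshold = 0.05) {
  union <- rbind(peaks_gm[, c("gene_id", "chrom", "strand", "s_start", "s_end")],
                 peaks_d4[, c("gene_id", "chrom", "strand", "s_start", "s_end")])
  if (!nrow(union))
    return(data.frame())
  win <- wcm$windows
  width <- attr(win, "width")
  gm <- condition_counts(wcm, "GM")
  d4 <- condition_counts(wcm, "D4")

  merged <- list()
  for (gid in unique(union$gene_id)) {
    iv <- union[union$gene_id == gid, ]
    iv <- iv[order(iv$s_start), ]
    grp <- cumsum(c(1L, tail(iv$s_start, -1) > head(cummax(iv$s_end), -1)))
    for (mem in split(seq_len(nrow(iv)), grp)) {
      merged[[length(merged) + 1L]] <- data.frame(
        gene_id = gid, chrom = iv$chrom[1], strand = iv$strand[1],
        s_start = min(iv$s_start[mem]), s_end = max(iv$s_end[mem]),
        stringsAsFactors = FALSE)
    }
  }
  mg <- do.call(rbind, merged)

  # Counts entering the Fisher test are rescaled to a common library depth
  # (the raw 2x2 is otherwise confounded by IP-versus-input depth imbalance
  # across conditions) and converted to effective counts that keep each
  # condition's IP:input ratio but carry the NB log-odds information
  # 1/x_ip + 1/x_in + 2*alpha/r.
  depth <- exp(mean(log(c(gm$N_ip, gm$N_in, d4$N_ip, d4$N_in))))
  alpha_hat <- estimate_window_dispersion(wcm)
  nrep <- max(table(wcm$libs$condition[wcm$libs$assay == "ip"]))
  eff <- function(x_ip, N_ip, x_in, N_in) {
    a_ip <- x_ip * depth / N_ip + 0.5
    a_in <- x_in * depth / N_in + 0.5
    s2 <- 1 / a_ip + 1 / a_in + 2 * alpha_hat / nrep
    e_in <- (1 + a_in / a_ip) / s2
    c(ip = round(e_in * a_ip / a_in), input = round(e_in))
  }

  n <- nrow(mg)
  lev_gm <- lev_d4 <- pval <- numeric(n)
  g_start <- g_end <- integer(n)
  for (i in seq_len(n)) {
    dj <- disjoint_windows(win, mg$gene_id[i], mg$s_start[i], mg$s_end[i], width)
    if (!length(dj))
      stop("merged peak on ", mg$gene_id[i], " overlaps no window (bookkeeping bug)")
    xg_ip <- sum(gm$x_ip[dj]); xg_in <- sum(gm$x_in[dj])
    xd_ip <- sum(d4$x_ip[dj]); xd_in <- sum(d4$x_in[dj])
    lev_gm[i] <- m6a_level(xg_ip, xg_in, gm$N_ip, gm$N_in)
    lev_d4[i] <- m6a_level(xd_ip, xd_in, d4$N_ip, d4$N_in)
    eg <- eff(xg_ip, gm$N_ip, xg_in, gm$N_in)
    ed <- eff(xd_ip, d4$N_ip, xd_in, d4$N_in)
    pval[i] <- diff_peak_test(eg[["ip"]], eg[["input"]],
                              ed[["ip"]], ed[["input"]])
    all_w <- which(win$gene_id == mg$gene_id[i] &
                   win$s_start < mg$s_end[i] & win$s_end > mg$s_start[i])
    g_start[i] <- min(win$g_start[all_w]); g_end[i] <- max(win$g_end[all_w])
  }
  q <- p.adjust(pval, "BH")
  lfc <- lev_d4 - lev_gm
  status <- rep("ns", n)
  status[q <= q_threshold & lfc > 0] <- "hyper"
  status[q <= q_threshold & lfc < 0] <- "hypo"
  out <- data.frame(gene_id = mg$gene_id, chrom = mg$chrom, strand = mg$strand,
                    start = g_start, end = g_end,
                    s_start = mg$s_start, s_end = mg$s_end,
                    m6a_level_GM = lev_gm, m6a_level_D4 = lev_d4,
                    diff_log2_fc = lfc, pvalue = pval, diff_fdr = q,
                    diff_lg_fdr = log10(q), status = status,
                    stringsAsFactors = FALSE)
  stage_log("differential_peaks", "%d union peaks: %d hyper, %d hypo",
            n, sum(status == "hyper"), sum(status == "hypo"))
  out
}

#' Write peaks as BED6+3
#'
#' Extra columns: gene_id, m6a_level, fdr.
#'
#' @param peaks A [call_peaks()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- peaks
  df$gene_id2 <- df$gene_id
  write_bed6(df, path, extra = c("gene_id2", "m6a_level", "fdr"))
}
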