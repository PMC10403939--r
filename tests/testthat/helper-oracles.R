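# Brute-force reference implementations, deliberately written in plain
# base R with explicit loops so they share no code path with the package.

oracle_classify <- function(hits, cat_by_taxid, e_thr = 1e-05) {
  if (nrow(hits) == 0) return("no_hit")
  cat <- unname(cat_by_taxid[as.character(hits$subject_taxon)])
  cat[is.na(cat)] <- "other"
  pass <- hits$evalue <= e_thr
  best_of <- function(idx) {
    if (length(idx) == 0) return(NA_integer_)
    b <- idx[1]
    for (i in idx) {
      if (hits$evalue[i] < hits$evalue[b] ||
          (hits$evalue[i] == hits$evalue[b] && hits$bitscore[i] > hits$bitscore[b])) {
        b <- i
      }
    }
    b
  }
  bv <- best_of(which(cat == "viral"))
  if (!is.na(bv) && pass[bv]) {
    demoted <- FALSE
    for (i in which(cat != "viral")) {
      if (hits$evalue[i] < hits$evalue[bv] ||
          (hits$evalue[i] == hits$evalue[bv] && hits$bitscore[i] >= hits$bitscore[bv])) {
        demoted <- TRUE
      }
    }
    if (!demoted) return("viral")
  }
  # best passing hit; residual full ties prefer a non-viral subject,
  # consistent with the demotion rule
  bp <- NA_integer_
  for (i in which(pass)) {
    if (is.na(bp)) { bp <- i; next }
    better <- hits$evalue[i] < hits$evalue[bp] ||
      (hits$evalue[i] == hits$evalue[bp] && hits$bitscore[i] > hits$bitscore[bp]) ||
      (hits$evalue[i] == hits$evalue[bp] && hits$bitscore[i] == hits$bitscore[bp] &&
         cat[i] != "viral" && cat[bp] == "viral")
    if (better) bp <- i
  }
  if (is.na(bp)) return("no_hit")
  if (cat[bp] %in% c("eukaryote_braconid", "eukaryote_other")) "eukaryotic" else "other"
}

oracle_contig_counts <- function(calls, loci, busco) {
  contigs <- sort(unique(loci$contig_id))
  out <- NULL
  for (cg in contigs) {
    genes <- unique(loci$gene_id[loci$contig_id == cg])
    st <- calls$status[match(genes, calls$gene_id)]
    bc <- calls$best_category[match(genes, calls$gene_id)]
    out <- rbind(out, data.frame(
      contig_id = cg,
      n_genes = length(genes),
      n_viral = sum(st == "viral", na.rm = TRUE),
      n_eukaryotic = sum(st == "eukaryotic", na.rm = TRUE),
      n_braconid = sum(st == "eukaryotic" & bc == "eukaryote_braconid", na.rm = TRUE),
      n_busco = sum(genes %in% busco)
    ))
  }
  out
}

oracle_hic <- function(pairs, viral) {
  total <- 0; inv <- 0; vv <- 0
  for (i in seq_len(nrow(pairs))) {
    a_v <- pairs$contig_a[i] %in% viral
    b_v <- pairs$contig_b[i] %in% viral
    total <- total + pairs$count[i]
    if (a_v || b_v) inv <- inv + pairs$count[i]
    if (a_v && b_v) vv <- vv + pairs$count[i]
  }
  c(f_involved = inv / total,
    f_viral_viral = if (inv > 0) vv / inv else NA_real_)
}

# exact two-sided rank-sum p by exhaustive enumeration of all
# choose(n, nx) assignments of the pooled ranks to the first sample
oracle_wilcoxon_exact <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  all_w <- apply(utils::combn(length(pooled), nx), 2, function(idx) {
    sum(ranks[idx]) - nx * (nx + 1) / 2
  })
  p_lo <- mean(all_w <= w_obs)
  p_hi <- mean(all_w >= w_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# tip-to-tip distance as depth(a) + depth(b) - 2 depth(mrca), with the
# MRCA found by intersecting full ancestor sets
oracle_path_length <- function(tree, a, b) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  for (i in seq_len(nrow(tree$edge))) {
    parent[tree$edge[i, 2]] <- tree$edge[i, 1]
    elen[tree$edge[i, 2]] <- tree$edge.length[i]
  }
  ancestors <- function(node) {
    out <- node
    while (node != root) {
      node <- parent[node]
      out <- c(out, node)
    }
    out
  }
  depth <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent[node]
    }
    d
  }
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  common <- intersect(ancestors(ia), ancestors(ib))
  mrca <- common[which.max(vapply(common, depth, numeric(1)))]
  depth(ia) + depth(ib) - 2 * depth(mrca)
}

oracle_windows <- function(depth, w, s) {
  len <- length(depth)
  out <- NULL
  start <- 1
  while (start + w - 1 <= len) {
    out <- rbind(out, c(start, mean(depth[start:(start + w - 1)])))
    start <- start + s
  }
  if (start <= len) out <- rbind(out, c(start, mean(depth[start:len])))
  out
}

oracle_zero_regions <- function(depth) {
  out <- NULL
  i <- 1
  while (i <= length(depth)) {
    if (depth[i] == 0) {
      j <- i
      while (j < length(depth) && depth[j + 1] == 0) j <- j + 1
      out <- rbind(out, c(start = i, end = j))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

oracle_hard_filter_row <- function(r, t) {
  ok <- function(x, f) is.na(x) || f(x)
  snp <- nchar(r$ref) == 1 && all(nchar(strsplit(r$alt, ",")[[1]]) == 1)
  total <- r$ad_ref + r$ad_alt
  maf_pass <- !is.na(total) && total > 0 &&
    (min(r$ad_ref, r$ad_alt) / total) >= t$maf_min
  snp &&
    ok(r$qd, function(x) x >= t$qd_min) &&
    ok(r$qual, function(x) x >= t$qual_min) &&
    ok(r$sor, function(x) x <= t$sor_max) &&
    ok(r$fs, function(x) x <= t$fs_max) &&
    ok(r$mq, function(x) x >= t$mq_min) &&
    ok(r$mq_rank_sum, function(x) x >= t$mqranksum_min) &&
    ok(r$read_pos_rank_sum, function(x) x >= t$readposranksum_min) &&
    maf_pass
}

oracle_best_blast <- function(hits) {
  keep <- logical(nrow(hits))
  for (q in unique(hits$query_id)) {
    idx <- which(hits$query_id == q)
    b <- idx[1]
    for (i in idx) {
      if (hits$evalue[i] < hits$evalue[b] ||
          (hits$evalue[i] == hits$evalue[b] && hits$bitscore[i] > hits$bitscore[b])) {
        b <- i
      }
    }
    keep[b] <- TRUE
  }
  which(keep)
}

random_hit_table <- function(gene_id, taxids, n_max = 6) {
  n <- sample.int(n_max, 1)
  tibble::tibble(
    query_id = gene_id,
    subject_id = sprintf("s%d", seq_len(n)),
    subject_taxon = sample(taxids, n, replace = TRUE),
    evalue = 10^stats::runif(n, -20, 0),
    bitscore = round(stats::runif(n, 30, 300), 1)
  )
}

default_taxa <- tibble::tibble(
  taxid = c(1L, 2L, 3L, 4L, 5L),
  category = c("viral", "eukaryote_braconid", "eukaryote_other",
               "bacterial", "other")
)
cat_by_taxid <- setNames(default_taxa$category, default_taxa$taxid)
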