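# Independent brute-force oracles. These deliberately re-derive every rule
# with naive loops and no package helpers, so that agreement with the
# production code is a real two-route check.

# ---- classification oracle --------------------------------------------------

.o_junctions <- function(exons) {
  n <- nrow(exons)
  if (n < 2L) return(NULL)
  cbind(exons[seq_len(n - 1L), 2L], exons[2:n, 1L])
}

.o_same_chain <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  nrow(a) == nrow(b) && all(a == b)
}

.o_subchain <- function(sub, full) {
  # consecutive proper subsequence, by sliding window
  if (is.null(sub) || is.null(full)) return(FALSE)
  ns <- nrow(sub); nf <- nrow(full)
  if (ns == 0L || ns >= nf) return(FALSE)
  for (o in 0:(nf - ns)) {
    if (all(full[(o + 1L):(o + ns), ] == sub)) return(TRUE)
  }
  FALSE
}

.o_overlap_nt <- function(exons, tx_exons) {
  tot <- 0L
  for (i in seq_len(nrow(exons))) for (k in seq_len(nrow(tx_exons))) {
    lo <- max(exons[i, 1L], tx_exons[k, 1L])
    hi <- min(exons[i, 2L], tx_exons[k, 2L])
    if (hi > lo) tot <- tot + (hi - lo)
  }
  tot
}

oracle_classify <- function(chrom, strand, exons, ann, end_fuzz = 100L) {
  txs <- ann$transcripts
  qj <- .o_junctions(exons)
  qspan <- c(exons[1L, 1L], exons[nrow(exons), 2L])
  # per-gene same-strand exonic overlap
  ov <- list()
  for (t in txs) {
    if (t$chrom != chrom || t$strand != strand) next
    o <- .o_overlap_nt(exons, t$exons)
    if (o > 0L) ov[[t$gene_id]] <- max(o, ov[[t$gene_id]] %||% 0L)
  }
  # recompute per-gene total overlap over the gene's exon union
  gene_ov <- list()
  for (g in names(ann$genes)) {
    ge <- do.call(rbind, lapply(ann$genes[[g]], function(id) {
      t <- txs[[id]]
      if (t$chrom == chrom && t$strand == strand) t$exons else NULL
    }))
    if (is.null(ge)) next
    # merge union intervals naively
    ge <- ge[order(ge[, 1L]), , drop = FALSE]
    merged <- ge[1L, , drop = FALSE]
    if (nrow(ge) > 1L) for (i in 2:nrow(ge)) {
      if (ge[i, 1L] <= merged[nrow(merged), 2L])
        merged[nrow(merged), 2L] <- max(merged[nrow(merged), 2L], ge[i, 2L])
      else merged <- rbind(merged, ge[i, ])
    }
    o <- .o_overlap_nt(exons, merged)
    if (o > 0L) gene_ov[[g]] <- o
  }
  if (length(gene_ov)) {
    cand <- names(gene_ov)[order(-unlist(gene_ov), names(gene_ov))]
    cand_tx <- unlist(lapply(cand, function(g) ann$genes[[g]]))
    if (!is.null(qj)) {
      for (id in cand_tx)
        if (.o_same_chain(qj, .o_junctions(txs[[id]]$exons)))
          return(list(category = "FSM", gene_id = txs[[id]]$gene_id))
      for (id in cand_tx)
        if (.o_subchain(qj, .o_junctions(txs[[id]]$exons)))
          return(list(category = "ISM", gene_id = txs[[id]]$gene_id))
      g <- cand[1L]
      don <- c(); acc <- c()
      for (id in ann$genes[[g]]) {
        j <- .o_junctions(txs[[id]]$exons)
        if (is.null(j)) next
        if (strand == "+") { don <- c(don, j[, 1L]); acc <- c(acc, j[, 2L]) }
        else { don <- c(don, j[, 2L]); acc <- c(acc, j[, 1L]) }
      }
      qd <- if (strand == "+") qj[, 1L] else qj[, 2L]
      qa <- if (strand == "+") qj[, 2L] else qj[, 1L]
      if (all(qd %in% don) && all(qa %in% acc))
        return(list(category = "NIC", gene_id = g))
      return(list(category = "NNC", gene_id = g))
    }
    # mono-exon
    for (g in cand) for (id in ann$genes[[g]]) {
      t <- txs[[id]]
      if (nrow(t$exons) == 1L &&
          abs(t$exons[1L, 1L] - qspan[1L]) <= end_fuzz &&
          abs(t$exons[1L, 2L] - qspan[2L]) <= end_fuzz)
        return(list(category = "FSM", gene_id = g))
    }
    for (g in cand) for (id in ann$genes[[g]]) {
      t <- txs[[id]]
      for (i in seq_len(nrow(t$exons)))
        if (t$exons[i, 1L] <= qspan[1L] && t$exons[i, 2L] >= qspan[2L])
          return(list(category = "ISM", gene_id = g))
    }
    return(list(category = "genic", gene_id = cand[1L]))
  }
  # no same-strand exonic overlap
  for (t in txs)
    if (t$chrom == chrom && t$strand != strand &&
        .o_overlap_nt(exons, t$exons) > 0L)
      return(list(category = "antisense", gene_id = NULL))
  # loci overlapping the span (any strand)
  loci <- list()
  for (g in names(ann$genes)) {
    ge <- do.call(rbind, lapply(ann$genes[[g]], function(id)
      if (txs[[id]]$chrom == chrom) txs[[id]]$exons else NULL))
    if (is.null(ge)) next
    sp <- c(min(ge[, 1L]), max(ge[, 2L]))
    if (sp[1L] < qspan[2L] && qspan[1L] < sp[2L]) loci[[g]] <- sp
  }
  if (length(loci) >= 2L) {
    sps <- do.call(rbind, loci)
    sps <- sps[order(sps[, 1L]), , drop = FALSE]
    k <- 1L; reach <- sps[1L, 2L]
    if (nrow(sps) > 1L) for (i in 2:nrow(sps)) {
      if (sps[i, 1L] >= reach) k <- k + 1L
      reach <- max(reach, sps[i, 2L])
    }
    if (k >= 2L) return(list(category = "fusion", gene_id = NULL))
  }
  if (length(loci)) {
    for (g in names(loci)) for (id in ann$genes[[g]]) {
      j <- .o_junctions(txs[[id]]$exons)
      if (is.null(j)) next
      for (i in seq_len(nrow(j)))
        if (j[i, 1L] <= qspan[1L] && qspan[2L] <= j[i, 2L])
          return(list(category = "genic_intron", gene_id = g))
    }
    return(list(category = "genic", gene_id = names(loci)[1L]))
  }
  list(category = "intergenic", gene_id = NULL)
}

# random structural queries over an annotation (mix of all expected kinds)
make_queries <- function(ann, n, seed) {
  set.seed(seed)
  tx_ids <- names(ann$transcripts)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t <- ann$transcripts[[sample(tx_ids, 1L)]]
    E <- t$exons; ne <- nrow(E)
    kind <- sample(c("fsm", "ism", "skip", "shift", "mono", "anti",
                     "random", "intron"), 1L,
                   prob = c(.2, .15, .15, .15, .1, .1, .1, .05))
    q <- switch(kind,
      fsm = list(t$chrom, t$strand, E),
      ism = if (ne >= 3L) {
        k <- sample(2:(ne - 1L), 1L)
        list(t$chrom, t$strand, E[k:ne, , drop = FALSE])
      } else list(t$chrom, t$strand, E),
      skip = if (ne >= 3L) {
        k <- sample(2:(ne - 1L), 1L)
        list(t$chrom, t$strand, E[-k, , drop = FALSE])
      } else list(t$chrom, t$strand, E),
      shift = {
        E2 <- E
        k <- sample(seq_len(ne - 1L), 1L)
        E2[k, 2L] <- E2[k, 2L] + sample(c(-7L, 13L), 1L)
        list(t$chrom, t$strand, E2)
      },
      mono = {
        k <- sample(seq_len(ne), 1L)
        pad <- sample(0:30, 2L, replace = TRUE)
        list(t$chrom, t$strand,
             cbind(E[k, 1L] + pad[1L],
                   max(E[k, 1L] + pad[1L] + 20L, E[k, 2L] - pad[2L])))
      },
      anti = list(t$chrom, if (t$strand == "+") "-" else "+", E),
      random = {
        s <- sample(1:5000, 1L)
        list(t$chrom, t$strand, cbind(s, s + sample(100:400, 1L)))
      },
      intron = if (ne >= 2L) {
        s <- E[1L, 2L] + 20L
        list(t$chrom, t$strand, cbind(s, min(s + 50L, E[2L, 1L] - 5L)))
      } else list(t$chrom, t$strand, E))
    if (q[[3L]][1L, 1L] >= q[[3L]][1L, 2L]) q[[3L]] <- E
    out[[i]] <- list(chrom = q[[1L]], strand = q[[2L]], exons = q[[3L]])
  }
  out
}

# ---- event oracle -----------------------------------------------------------

oracle_events <- function(transcripts) {
  # exhaustive pairwise enumeration; returns data.table(event_type, coords)
  strand <- transcripts[[1L]]$strand
  xs <- lapply(transcripts, function(t)
    list(id = t$transcript_id, e = t$exons, j = .o_junctions(t$exons)))
  found <- character(0)
  keyify <- function(type, v) paste(type, paste(v, collapse = ";"))
  n <- length(xs)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    A <- xs[[i]]; B <- xs[[k]]
    if (is.null(B$j)) next
    for (r in seq_len(nrow(B$j))) {
      d <- B$j[r, 1L]; a <- B$j[r, 2L]
      # ES
      ie <- which(A$e[, 2L] == d); is <- which(A$e[, 1L] == a)
      if (length(ie) == 1L && length(is) == 1L && is - ie >= 2L)
        found <- c(found, keyify("ES", c(d, A$e[ie + 1L, 1L],
                                         A$e[is - 1L, 2L], a)))
      # RI: A has exon spanning (d,a) with matching outer edges of B's flanks
      ib <- which(B$e[, 2L] == d)
      if (length(ib) == 1L && ib < nrow(B$e) && B$e[ib + 1L, 1L] == a) {
        s <- B$e[ib, 1L]; e2 <- B$e[ib + 1L, 2L]
        if (any(A$e[, 1L] == s & A$e[, 2L] == e2))
          found <- c(found, keyify("RI", c(s, d, a, e2)))
      }
      # pairs of junctions sharing one side
      if (!is.null(A$j)) for (r2 in seq_len(nrow(A$j))) {
        d2 <- A$j[r2, 1L]; a2 <- A$j[r2, 2L]
        if (a2 == a && d2 != d) {
          fe1 <- NULL; fe2 <- NULL; fl1 <- c(FALSE, FALSE); fl2 <- c(FALSE, FALSE)
          for (x in xs) {
            if (!is.null(x$j)) for (rr in seq_len(nrow(x$j))) {
              if (x$j[rr, 1L] == d && x$j[rr, 2L] == a) {
                ii <- which(x$e[, 2L] == d)
                for (q in ii) {
                  fe1 <- rbind(fe1, x$e[q, ])
                  if (q == 1L) fl1[1L] <- TRUE
                  if (q == nrow(x$e)) fl1[2L] <- TRUE
                }
              }
              if (x$j[rr, 1L] == d2 && x$j[rr, 2L] == a) {
                ii <- which(x$e[, 2L] == d2)
                for (q in ii) {
                  fe2 <- rbind(fe2, x$e[q, ])
                  if (q == 1L) fl2[1L] <- TRUE
                  if (q == nrow(x$e)) fl2[2L] <- TRUE
                }
              }
            }
          }
          if (!is.null(fe1) && !is.null(fe2)) {
            lo1 <- min(fe1[, 1L]); hi1 <- max(fe1[, 2L])
            lo2 <- min(fe2[, 1L]); hi2 <- max(fe2[, 2L])
            dd <- sort(c(d, d2))
            if (lo1 < hi2 && lo2 < hi1) {
              found <- c(found, keyify(if (strand == "+") "A5" else "A3",
                                       c(dd[1L], dd[2L], a)))
            } else if (d < d2) {
              if (fl1[1L] && fl2[1L])
                found <- c(found, keyify(if (strand == "+") "AF" else "AL",
                                         c(lo1, d, lo2, d2, a)))
            }
          }
        }
        if (d2 == d && a2 != a) {
          fe1 <- NULL; fe2 <- NULL; fl1 <- c(FALSE, FALSE); fl2 <- c(FALSE, FALSE)
          aa <- sort(c(a, a2)); a_lo <- aa[1L]; a_hi <- aa[2L]
          for (x in xs) {
            if (!is.null(x$j)) for (rr in seq_len(nrow(x$j))) {
              if (x$j[rr, 1L] == d && x$j[rr, 2L] == a_lo) {
                ii <- which(x$e[, 1L] == a_lo)
                for (q in ii) {
                  fe1 <- rbind(fe1, x$e[q, ])
                  if (q == 1L) fl1[1L] <- TRUE
                  if (q == nrow(x$e)) fl1[2L] <- TRUE
                }
              }
              if (x$j[rr, 1L] == d && x$j[rr, 2L] == a_hi) {
                ii <- which(x$e[, 1L] == a_hi)
                for (q in ii) {
                  fe2 <- rbind(fe2, x$e[q, ])
                  if (q == 1L) fl2[1L] <- TRUE
                  if (q == nrow(x$e)) fl2[2L] <- TRUE
                }
              }
            }
          }
          if (!is.null(fe1) && !is.null(fe2)) {
            lo1 <- min(fe1[, 1L]); hi1 <- max(fe1[, 2L])
            lo2 <- min(fe2[, 1L]); hi2 <- max(fe2[, 2L])
            if (lo1 < hi2 && lo2 < hi1) {
              found <- c(found, keyify(if (strand == "+") "A3" else "A5",
                                       c(d, a_lo, a_hi)))
            } else {
              if (fl1[2L] && fl2[2L])
                found <- c(found, keyify(if (strand == "+") "AL" else "AF",
                                         c(d, a_lo, hi1, a_hi, hi2)))
            }
          }
        }
      }
      # MX: consecutive junction paths D-e1-A vs D-e2-A
      if (r < nrow(B$j) && !is.null(A$j)) {
        D <- B$j[r, 1L]; b_a <- B$j[r, 2L]
        b_d <- B$j[r + 1L, 1L]; A2 <- B$j[r + 1L, 2L]
        if (any(B$e[, 1L] == b_a & B$e[, 2L] == b_d)) {
          for (r2 in seq_len(nrow(A$j) - 1L)) {
            if (A$j[r2, 1L] != D || A$j[r2 + 1L, 2L] != A2) next
            o_a <- A$j[r2, 2L]; o_d <- A$j[r2 + 1L, 1L]
            if (!any(A$e[, 1L] == o_a & A$e[, 2L] == o_d)) next
            if (o_a == b_a && o_d == b_d) next
            if (!(b_d <= o_a || o_d <= b_a)) next
            co <- vapply(xs, function(x)
              any(x$e[, 1L] == b_a & x$e[, 2L] == b_d) &&
                any(x$e[, 1L] == o_a & x$e[, 2L] == o_d), TRUE)
            if (any(co)) next
            e1 <- c(b_a, b_d); e2 <- c(o_a, o_d)
            if (e1[1L] > e2[1L]) { tmp <- e1; e1 <- e2; e2 <- tmp }
            found <- c(found, keyify("MX", c(D, e1, e2, A2)))
          }
        }
      }
    }
  }
  unique(found)
}

# ---- ORF oracle -------------------------------------------------------------

oracle_orf <- function(seq, min_codons = 100L) {
  codons <- c(TAA = TRUE, TAG = TRUE, TGA = TRUE)
  n <- nchar(seq)
  best <- NULL
  for (p in seq_len(n - 2L)) {
    if (substr(seq, p, p + 2L) != "ATG") next
    q <- p + 3L
    while (q + 2L <= n) {
      cod <- substr(seq, q, q + 2L)
      if (!is.na(codons[cod])) {
        len <- (q - p) %/% 3L
        if (is.null(best) || len > best$len) best <- list(start = p, len = len)
        break
      }
      q <- q + 3L
    }
  }
  if (is.null(best) || best$len < min_codons) return(NULL)
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
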