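## Local alternative-splicing event detection among the transcripts of one
## gene (SUPPA-style local events, seven types), plus a novelty-stratified
## summary.
##
## Types (strand-aware; a "donor" is the biological 5' splice site):
##   ES : a junction (d,a) in one transcript vs >=1 complete exon between
##        d and a in another that uses both flanking sites
##   A5 : two junctions share their acceptor side and differ at the donor,
##        with overlapping flanking exons
##   A3 : mirror of A5 at the acceptor
##   AF : distinct, non-overlapping first exons splicing to a shared
##        downstream acceptor
##   AL : distinct, non-overlapping last exons spliced from a shared donor
##   RI : one transcript's exon spans another's junction with both outer
##        exon edges matching
##   MX : two non-overlapping single-exon alternatives between a shared
##        donor and acceptor, never co-occurring in one chain
## Events are deduplicated by (type, coordinates); inclusion/exclusion sets
## collect every transcript matching the respective pattern.

.tx_struct <- function(t) {
  j <- junction_chain(t)
  list(id = t$transcript_id, strand = t$strand, exons = t$exons, j = j,
       jstr = if (nrow(j)) paste(j[, 1L], j[, 2L], sep = "-") else character(0))
}

#' Detect local AS events among a gene's transcripts
#'
#' @param transcripts list of `transcript_model`s of one gene (same
#'   chrom/strand).
#' @param gene_id optional gene label carried into the result.
#' @return `data.table` with `event_type`, `gene_id`, `coords`
#'   (type-specific, semicolon-joined integers), `inclusion`, `exclusion`
#'   (comma-joined transcript ids). Zero rows when fewer than two
#'   transcripts.
#' @export
detect_events <- function(transcripts, gene_id = NA_character_) {
  empty <- data.table::data.table(event_type = character(0),
                                  gene_id = character(0), coords = character(0),
                                  inclusion = character(0), exclusion = character(0))
  if (length(transcripts) < 2L) return(empty)
  strand <- transcripts[[1L]]$strand
  tx <- lapply(transcripts, .tx_struct)
  tx <- tx[order(vapply(tx, `[[`, "", "id"))]
  n <- length(tx)
  has_junction <- function(t, d, a) any(t$j[, 1L] == d & t$j[, 2L] == a)
  events <- list()
  add <- function(type, coords, inc, exc) {
    key <- paste(type, paste(coords, collapse = ";"))
    events[[key]] <<- list(event_type = type, coords = paste(coords, collapse = ";"),
                           inclusion = sort(unique(inc)), exclusion = sort(unique(exc)))
  }

  ## ES + RI + MX: driven by each transcript's junctions
  for (b in seq_len(n)) {
    tb <- tx[[b]]
    if (!nrow(tb$j)) next
    for (k in seq_len(nrow(tb$j))) {
      d <- tb$j[k, 1L]; a <- tb$j[k, 2L]
      ## ES: another transcript has exon(s) strictly between d and a, using
      ## both flanking sites
      for (i in seq_len(n)) {
        ti <- tx[[i]]
        id_end <- which(ti$exons[, 2L] == d)
        ia_start <- which(ti$exons[, 1L] == a)
        if (length(id_end) == 1L && length(ia_start) == 1L &&
            ia_start - id_end >= 2L) {
          sk_s <- ti$exons[id_end + 1L, 1L]
          sk_e <- ti$exons[ia_start - 1L, 2L]
          inc <- vapply(tx, function(t) {
            ie <- which(t$exons[, 2L] == d); is <- which(t$exons[, 1L] == a)
            length(ie) == 1L && length(is) == 1L && is - ie >= 2L &&
              t$exons[ie + 1L, 1L] == sk_s && t$exons[is - 1L, 2L] == sk_e
          }, TRUE)
          exc <- vapply(tx, has_junction, TRUE, d = d, a = a)
          add("ES", c(d, sk_s, sk_e, a),
              vapply(tx[inc], `[[`, "", "id"), vapply(tx[exc], `[[`, "", "id"))
        }
      }
      ## RI: another transcript has one exon spanning (d,a) with matching
      ## outer edges
      ib <- which(tb$exons[, 2L] == d)   # upstream flanking exon in tb
      if (length(ib) == 1L && ib < nrow(tb$exons) &&
          tb$exons[ib + 1L, 1L] == a) {
        s <- tb$exons[ib, 1L]; e <- tb$exons[ib + 1L, 2L]
        ret <- vapply(tx, function(t)
          any(t$exons[, 1L] == s & t$exons[, 2L] == e), TRUE)
        if (any(ret)) {
          spl <- vapply(tx, function(t) {
            ii <- which(t$exons[, 1L] == s & t$exons[, 2L] == d)
            length(ii) == 1L && ii < nrow(t$exons) &&
              t$exons[ii + 1L, 1L] == a && t$exons[ii + 1L, 2L] == e
          }, TRUE)
          add("RI", c(s, d, a, e),
              vapply(tx[ret], `[[`, "", "id"), vapply(tx[spl], `[[`, "", "id"))
        }
      }
    }
  }

  ## A5/A3/AF/AL: pairs of junctions sharing one boundary
  all_j <- unique(do.call(rbind, lapply(tx, function(t) t$j)))
  if (!is.null(all_j) && nrow(all_j) >= 2L) {
    for (i in seq_len(nrow(all_j) - 1L)) for (jj in (i + 1L):nrow(all_j)) {
      j1 <- all_j[i, ]; j2 <- all_j[jj, ]
      share_right <- j1[2L] == j2[2L] && j1[1L] != j2[1L]
      share_left <- j1[1L] == j2[1L] && j1[2L] != j2[2L]
      if (!share_right && !share_left) next
      if (share_right) {
        ## alternative genomic-left boundary: find flanking exons ending there
        a <- j1[2L]
        d1 <- min(j1[1L], j2[1L]); d2 <- max(j1[1L], j2[1L])
        f1 <- .flank_exons(tx, d1, side = "end", other = a)
        f2 <- .flank_exons(tx, d2, side = "end", other = a)
        if (is.null(f1) || is.null(f2)) next
        overlap <- f1$lo < f2$hi && f2$lo < f1$hi
        set1 <- .tx_with_junction(tx, d1, a)
        set2 <- .tx_with_junction(tx, d2, a)
        if (overlap) {
          type <- if (strand == "+") "A5" else "A3"
          add(type, c(d1, d2, a), set1, set2)
        } else if (f1$first && f2$first) {
          ## genomic-upstream terminal exons: biological first on "+",
          ## biological last on "-"
          add(if (strand == "+") "AF" else "AL",
              c(f1$lo, d1, f2$lo, d2, a), set1, set2)
        }
      } else {
        d <- j1[1L]
        a1 <- min(j1[2L], j2[2L]); a2 <- max(j1[2L], j2[2L])
        f1 <- .flank_exons(tx, a1, side = "start", other = d)
        f2 <- .flank_exons(tx, a2, side = "start", other = d)
        if (is.null(f1) || is.null(f2)) next
        overlap <- f1$lo < f2$hi && f2$lo < f1$hi
        set1 <- .tx_with_junction(tx, d, a1)
        set2 <- .tx_with_junction(tx, d, a2)
        if (overlap) {
          type <- if (strand == "+") "A3" else "A5"
          add(type, c(d, a1, a2), set1, set2)
        } else if (f1$last && f2$last) {
          ## genomic-downstream terminal exons: biological last on "+",
          ## biological first on "-"
          add(if (strand == "+") "AL" else "AF",
              c(d, a1, f1$hi, a2, f2$hi), set1, set2)
        }
      }
    }
  }

  ## MX: two single-exon alternatives between shared donor/acceptor
  for (i in seq_len(n)) for (jj in seq_len(n)) {
    ti <- tx[[i]]; tj2 <- tx[[jj]]
    if (nrow(ti$j) < 2L || nrow(tj2$j) < 2L) next
    for (p in seq_len(nrow(ti$j) - 1L)) {
      ## path D -> exon (a1,d1) -> A in ti (consecutive junctions)
      D <- ti$j[p, 1L]; a1 <- ti$j[p, 2L]
      d1 <- ti$j[p + 1L, 1L]; A <- ti$j[p + 1L, 2L]
      if (!any(ti$exons[, 1L] == a1 & ti$exons[, 2L] == d1)) next
      for (q in seq_len(nrow(tj2$j) - 1L)) {
        if (tj2$j[q, 1L] != D || tj2$j[q + 1L, 2L] != A) next
        a2 <- tj2$j[q, 2L]; d2 <- tj2$j[q + 1L, 1L]
        if (!any(tj2$exons[, 1L] == a2 & tj2$exons[, 2L] == d2)) next
        if (a1 == a2 && d1 == d2) next
        if (!(d1 <= a2 || d2 <= a1)) next        # alternatives must not overlap
        both <- vapply(tx, function(t)
          any(t$exons[, 1L] == a1 & t$exons[, 2L] == d1) &&
            any(t$exons[, 1L] == a2 & t$exons[, 2L] == d2), TRUE)
        if (any(both)) next
        path_tx <- function(aa, dd) vapply(tx, function(t)
          has_junction(t, D, aa) &&
            any(t$exons[, 1L] == aa & t$exons[, 2L] == dd) &&
            has_junction(t, dd, A), TRUE)
        e1 <- c(a1, d1); e2 <- c(a2, d2)
        if (e1[1L] > e2[1L]) { tmpv <- e1; e1 <- e2; e2 <- tmpv }
        add("MX", c(D, e1, e2, A),
            vapply(tx[path_tx(e1[1L], e1[2L])], `[[`, "", "id"),
            vapply(tx[path_tx(e2[1L], e2[2L])], `[[`, "", "id"))
      }
    }
  }

  if (!length(events)) return(empty)
  out <- data.table::rbindlist(lapply(events, function(e)
    data.table::data.table(event_type = e$event_type, gene_id = gene_id,
                           coords = e$coords,
                           inclusion = paste(e$inclusion, collapse = ","),
                           exclusion = paste(e$exclusion, collapse = ","))))
  data.table::setorder(out, event_type, coords)
  out[]
}

## exons flanking a shared junction boundary: all exons whose `side` edge
## equals `pos` in transcripts that carry a junction (pos-other or
## other-pos). Returns the union bounds and whether any such exon is a
## transcript-first/last exon (genomic order); NULL when absent.
.flank_exons <- function(tx, pos, side, other) {
  lo <- Inf; hi <- -Inf; first <- FALSE; last <- FALSE; found <- FALSE
  for (t in tx) {
    if (side == "end") {
      if (!any(t$j[, 1L] == pos & t$j[, 2L] == other)) next
      idx <- which(t$exons[, 2L] == pos)
    } else {
      if (!any(t$j[, 2L] == pos & t$j[, 1L] == other)) next
      idx <- which(t$exons[, 1L] == pos)
    }
    for (ii in idx) {
      found <- TRUE
      lo <- min(lo, t$exons[ii, 1L]); hi <- max(hi, t$exons[ii, 2L])
      if (ii == 1L) first <- TRUE
      if (ii == nrow(t$exons)) last <- TRUE
    }
  }
  if (!found) return(NULL)
  list(lo = lo, hi = hi, first = first, last = last)
}

.tx_with_junction <- function(tx, d, a) {
  hit <- vapply(tx, function(t) any(t$j[, 1L] == d & t$j[, 2L] == a), TRUE)
  vapply(tx[hit], `[[`, "", "id")
}

#' Summarize AS events by type and novelty stratum
#'
#' @param events `data.table` from [detect_events()] (possibly several
#'   genes row-bound).
#' @param novelty named character vector mapping transcript id to
#'   `"known"` or `"novel"`; must cover every participating transcript.
#' @return `data.table` with `event_type`, `stratum` (`novel` when >=1
#'   participating transcript is novel, else `known`) and `n`.
#' @export
summarize_events <- function(events, novelty) {
  types <- c("ES", "A5", "A3", "AF", "AL", "RI", "MX")
  if (!nrow(events)) {
    return(data.table::data.table(
      event_type = rep(types, 2L),
      stratum = rep(c("known", "novel"), each = length(types)), n = 0L))
  }
  tx_of <- function(e) unique(unlist(strsplit(c(e), ",", fixed = TRUE)))
  all_tx <- unique(unlist(strsplit(c(events$inclusion, events$exclusion),
                                   ",", fixed = TRUE)))
  missing <- setdiff(all_tx, names(novelty))
  if (length(missing))
    stop("transcripts missing from the novelty map: ",
         paste(missing, collapse = ", "))
  strat <- vapply(seq_len(nrow(events)), function(i) {
    tx <- tx_of(c(events$inclusion[i], events$exclusion[i]))
    if (any(novelty[tx] == "novel")) "novel" else "known"
  }, "")
  tab <- data.table::data.table(event_type = events$event_type, stratum = strat)
  counts <- tab[, .(n = .N), by = .(event_type, stratum)]
  grid <- data.table::CJ(event_type = types, stratum = c("known", "novel"))
  out <- merge(grid, counts, by = c("event_type", "stratum"), all.x = TRUE)
  out[is.na(n), n := 0L]
  out[]
}
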