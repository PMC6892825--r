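#' Pool per-subject GFP peaks with an even-contribution cap
#'
#' Concatenates GFP-peak topographies across subjects into one matrix
#' for global segmentation. Each subject contributes at most
#' `per_subject_cap` peaks (its largest-GFP ones), so long recordings
#' do not dominate the global maps. `cap = "auto"` uses the smallest
#' per-subject peak count, mirroring the shortest-file rule.
#'
#' @param peak_sets List of `ms_peaks` (see [extract_gfp_peaks()]).
#' @param per_subject_cap Positive integer, or `"auto"`.
#' @return A list of class `ms_pooled_peaks`: `maps` (pooled P x C),
#'   `gfp`, `subject_id` (per row), `cap`, `montage`.
#' @export
pool_peaks <- function(peak_sets, per_subject_cap = "auto") {
  if (length(peak_sets) == 0) {
    stop("`peak_sets` must contain at least one subject", call. = FALSE)
  }
  counts <- vapply(peak_sets, function(p) nrow(p$maps), 0L)
  cap <- if (identical(per_subject_cap, "auto")) {
    min(counts)
  } else {
    as.integer(per_subject_cap)
  }
  if (cap < 1) stop("Peak cap must be at least 1", call. = FALSE)
  picked <- lapply(peak_sets, function(p) {
    if (nrow(p$maps) <= cap) return(p)
    keep <- sort(order(p$gfp, decreasing = TRUE)[seq_len(cap)])
    list(maps = p$maps[keep, , drop = FALSE], gfp = p$gfp[keep],
         subject_id = p$subject_id, montage = p$montage)
  })
  structure(
    list(
      maps = do.call(rbind, lapply(picked, `[[`, "maps")),
      gfp = unlist(lapply(picked, `[[`, "gfp")),
      subject_id = rep(vapply(picked, `[[`, "", "subject_id"),
                       vapply(picked, function(p) nrow(p$maps), 0L)),
      cap = cap,
      montage = peak_sets[[1]]$montage
    ),
    class = "ms_pooled_peaks"
  )
}

#' Topographic atomize-and-agglomerate hierarchical clustering
#'
#' Bottom-up TAAHC of topographies: every map starts as a singleton
#' cluster; until `K_target` clusters remain, the cluster with the
#' lowest GEV contribution over its own members is atomized and each
#' freed map is reassigned to the surviving cluster whose prototype it
#' correlates with best (polarity-invariant). Prototypes are the first
#' principal component of the member maps (unit-norm; the PC of
#' zero-mean maps is itself average-reference consistent), which
#' aligns polarity implicitly. A cluster's GEV contribution is
#' `sum(gfp_p^2 * r(map_p, prototype)^2)` over its members.
#'
#' @param maps P x C matrix of peak topographies (average-referenced
#'   rows), or an `ms_pooled_peaks` / `ms_peaks` object.
#' @param K_target Number of clusters to keep (2 <= K_target < P).
#' @param criterion Worst-cluster criterion: `"gev"` (default) or
#'   `"mean_corr"` (lowest mean member correlation, an alternative
#'   convention).
#' @return A list of class `ms_taahc`: `maps` (an `ms_maps` with
#'   provenance `"taahc"`), `assignment` (per input row, 1..K), and
#'   `gev_contrib` per cluster.
#' @export
taahc <- function(maps, K_target, criterion = c("gev", "mean_corr")) {
  criterion <- match.arg(criterion)
  montage <- NULL
  if (inherits(maps, c("ms_pooled_peaks", "ms_peaks"))) {
    montage <- maps$montage
    maps <- maps$maps
  }
  maps <- as.matrix(maps)
  P <- nrow(maps)
  C <- ncol(maps)
  if (!(is.numeric(K_target) && K_target >= 2 && K_target < P)) {
    stop("Need 2 <= K_target < number of maps", call. = FALSE)
  }
  K_target <- as.integer(K_target)

  M <- maps - rowMeans(maps)
  w <- rowSums(M^2)                       # proportional to gfp^2
  nrm <- sqrt(w)
  if (any(nrm == 0)) stop("Zero-norm peak map", call. = FALSE)
  Mn <- M / nrm

  protoT <- t(Mn)                         # C x P, column j = prototype j
  active <- rep(TRUE, P)
  members <- as.list(seq_len(P))
  contrib <- w                            # singleton: r = 1
  score <- if (criterion == "gev") contrib else rep(1, P)

  update_cluster <- function(j) {
    m <- members[[j]]
    if (length(m) == 1) {
      pr <- Mn[m, ]
    } else {
      cp <- crossprod(Mn[m, , drop = FALSE])
      pr <- eigen(cp, symmetric = TRUE)$vectors[, 1]
    }
    protoT[, j] <<- pr
    r2 <- (Mn[m, , drop = FALSE] %*% pr)^2
    contrib[j] <<- sum(w[m] * r2)
    score[j] <<- if (criterion == "gev") contrib[j] else mean(sqrt(r2))
  }

  n_active <- P
  while (n_active > K_target) {
    worst <- which.min(replace(score, !active, Inf))
    freed <- members[[worst]]
    active[worst] <- FALSE
    members[worst] <- list(integer(0))
    n_active <- n_active - 1L

    sc <- abs(Mn[freed, , drop = FALSE] %*% protoT)
    sc[, !active] <- -1
    dest <- max.col(sc, ties.method = "first")
    for (j in unique(dest)) {
      members[[j]] <- c(members[[j]], freed[dest == j])
    }
    for (j in unique(dest)) update_cluster(j)
  }

  idx <- which(active)
  proto <- t(protoT[, idx, drop = FALSE])
  assignment <- integer(P)
  for (k in seq_along(idx)) assignment[members[[idx[k]]]] <- k
  if (is.null(montage) && C == 19) montage <- montage_1020()
  out_maps <- new_ms_maps(proto, montage = montage,
                          labels = paste0("map", seq_along(idx)),
                          provenance = "taahc")
  structure(
    list(maps = out_maps, assignment = assignment,
         gev_contrib = contrib[idx] / sum(w)),
    class = "ms_taahc"
  )
}

#' @export
print.ms_taahc <- function(x, ...) {
  cat(sprintf("<ms_taahc> %d clusters over %d peak maps\n",
              nrow(x$maps$maps), length(x$assignment)))
  invisible(x)
}

# all permutations of 1..n (n small)
permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(c(seq_len(n))[-i][sub], nrow(sub), n - 1))
  }))
}

#' Order estimated maps against canonical archetypes
#'
#' One-to-one assignment of estimated maps to the canonical archetype
#' templates maximising total polarity-invariant spatial correlation
#' (exact assignment by enumeration; K <= 8), then relabelling the maps
#' A, B, C, ... accordingly.
#'
#' @param ms An `ms_maps` (or `ms_taahc`) with K rows.
#' @param canonical An `ms_maps` template set with the same K and
#'   channel count.
#' @return An `ms_maps` whose row order and labels follow the canonical
#'   archetypes, with attribute `"match_corr"` giving each map's
#'   correlation to its archetype and `"perm"` the applied permutation
#'   (estimated row feeding each canonical slot).
#' @export
order_maps <- function(ms, canonical) {
  assignment <- NULL
  if (inherits(ms, "ms_taahc")) {
    assignment <- ms$assignment
    ms <- ms$maps
  }
  stopifnot(inherits(ms, "ms_maps"), inherits(canonical, "ms_maps"))
  K <- nrow(ms$maps)
  if (K != nrow(canonical$maps) || ncol(ms$maps) != ncol(canonical$maps)) {
    stop("Map set and canonical set differ in K or channel count",
         call. = FALSE)
  }
  S <- abs(stats::cor(t(canonical$maps), t(ms$maps)))  # K x K: canon x est
  perms <- permutations(K)
  tot <- apply(perms, 1, function(p) sum(S[cbind(seq_len(K), p)]))
  best <- perms[which.max(tot), ]
  out <- new_ms_maps(ms$maps[best, , drop = FALSE],
                     montage = ms$montage,
                     labels = canonical$labels,
                     provenance = ms$provenance)
  attr(out, "match_corr") <- S[cbind(seq_len(K), best)]
  attr(out, "perm") <- best
  if (!is.null(assignment)) {
    relabel <- match(seq_len(K), best)
    attr(out, "assignment") <- relabel[assignment]
  }
  out
}
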