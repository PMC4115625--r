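#' Extract suprathreshold clusters
#'
#' Connected components of `{t > threshold_t} & mask` under 6-, 18- or
#' 26-connectivity (faces; faces + edges; faces + edges + corners). Each
#' cluster reports its peak (maximum t, ties broken by first position in
#' scan order, i.e. column-major linear index) and its size in voxels.
#'
#' @param t_map 3D numeric statistic map (NA treated as subthreshold).
#' @param mask Logical 3D mask (default: everywhere).
#' @param threshold_t Finite cluster-forming threshold (use `-Inf` with a
#'   significance mask to cluster exactly the significant voxels).
#' @param connectivity 6, 18 or 26 (default 18).
#' @return A data.frame with columns `cluster`, `peak_x`, `peak_y`,
#'   `peak_z`, `peak_t`, `size_voxels`, ordered by decreasing peak t.
#' @export
clusterize <- function(t_map, mask = NULL, threshold_t, connectivity = 18L) {
  if (!connectivity %in% c(6L, 18L, 26L))
    stop_("`connectivity` must be 6, 18 or 26")
  dims <- dim(t_map)
  mask <- mask %||% array(TRUE, dims)
  supra <- !is.na(t_map) & t_map > threshold_t & mask
  supra[is.na(supra)] <- FALSE

  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  ord <- rowSums(abs(offs))
  offs <- offs[ord > 0 & ord <= switch(as.character(connectivity),
                                       "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]

  idx_supra <- which(supra)
  out <- data.frame(cluster = integer(0), peak_x = integer(0),
                    peak_y = integer(0), peak_z = integer(0),
                    peak_t = numeric(0), size_voxels = integer(0))
  if (length(idx_supra) == 0L) return(out)

  visited <- array(FALSE, dims)
  cl <- 0L
  for (start in idx_supra) {
    if (visited[start]) next
    cl <- cl + 1L
    stack <- start
    visited[start] <- TRUE
    members <- integer(0)
    while (length(stack) > 0L) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      members <- c(members, cur)
      cz <- (cur - 1L) %/% (dims[1] * dims[2])
      rem <- (cur - 1L) %% (dims[1] * dims[2])
      cy <- rem %/% dims[1]
      cx <- rem %% dims[1]
      nb <- cbind(cx + 1L + offs[, 1], cy + 1L + offs[, 2], cz + 1L + offs[, 3])
      nb <- nb[in_grid(nb, dims), , drop = FALSE]
      lin <- vox_linear(nb, dims)
      lin <- lin[supra[lin] & !visited[lin]]
      if (length(lin) > 0L) {
        visited[lin] <- TRUE
        stack <- c(stack, lin)
      }
    }
    members <- sort(members)
    peak <- members[which.max(t_map[members])]  # strict max, first in scan order
    pz <- (peak - 1L) %/% (dims[1] * dims[2])
    prem <- (peak - 1L) %% (dims[1] * dims[2])
    out <- rbind(out, data.frame(cluster = cl,
                                 peak_x = as.integer(prem %% dims[1] + 1L),
                                 peak_y = as.integer(prem %/% dims[1] + 1L),
                                 peak_z = as.integer(pz + 1L),
                                 peak_t = t_map[peak],
                                 size_voxels = length(members)))
  }
  out <- out[order(-out$peak_t), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Cohen's d (pooled standard deviation)
#'
#' `(mean_A - mean_B) / s_p` with
#' `s_p = sqrt(((nA - 1) s_A^2 + (nB - 1) s_B^2) / (nA + nB - 2))`.
#'
#' @param values_a,values_b Numeric vectors with at least 2 values each.
#' @return The standardized mean difference.
#' @examples
#' cohens_d(c(2, 4), c(1, 3)) # 1 / sqrt(2)
#' @export
cohens_d <- function(values_a, values_b) {
  na <- length(values_a); nb <- length(values_b)
  if (na < 2L || nb < 2L) stop_("at least 2 values per group are required")
  sp2 <- ((na - 1) * var(values_a) + (nb - 1) * var(values_b)) / (na + nb - 2)
  if (sp2 <= 0) stop_("pooled standard deviation is zero; d is undefined")
  (mean(values_a) - mean(values_b)) / sqrt(sp2)
}
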