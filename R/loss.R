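#' Detection loss over assigned anchors
#'
#' Classification is a sigmoid focal loss over positive and negative anchors
#' only — ignored anchors contribute nothing to the value or the gradient.
#' Regression is a smooth-L1 over the four encoded targets of positive
#' anchors only. Both terms are normalised by the number of positives
#' (at least 1), and `total = classification + lambda * regression`.
#'
#' @param head_out list of per-level head outputs from [forward()].
#' @param assignment an `anchor_assignment` aligned with the model's anchor
#'   ordering (from [assign_nearest()] or [assign_iou()] on anchors
#'   enumerated over the same patch).
#' @param alpha,gamma focal-loss shape parameters.
#' @param lambda weight of the regression term.
#' @param with_grad if `TRUE`, also return per-level gradients w.r.t. the
#'   head outputs, ready for [backward()].
#' @return List with `total`, `cls`, `reg` (finite scalars) and, when
#'   requested, `grad` (list of per-level arrays).
#' @export
detection_loss <- function(head_out, assignment, alpha = 0.25, gamma = 2,
                           lambda = 1, with_grad = FALSE) {
  flat <- flatten_head(head_out)
  n <- length(flat$logits)
  if (n != nrow(assignment))
    stop("assignment has ", nrow(assignment), " anchors but the head emits ", n)
  lab <- assignment$label
  pos <- which(lab == "positive")
  neg <- which(lab == "negative")
  n_pos <- max(1L, length(pos))

  p <- 1 / (1 + exp(-flat$logits))
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  cls_terms <- numeric(n)
  cls_terms[pos] <- -alpha * (1 - p[pos])^gamma * log(p[pos])
  cls_terms[neg] <- -(1 - alpha) * p[neg]^gamma * log(1 - p[neg])
  cls <- sum(cls_terms[c(pos, neg)]) / n_pos

  reg <- 0
  if (length(pos) > 0L) {
    tgt <- as.matrix(assignment[pos, c("dz", "dy", "dx", "dd")])
    err <- flat$reg[pos, , drop = FALSE] - tgt
    sl1 <- ifelse(abs(err) < 1, 0.5 * err^2, abs(err) - 0.5)
    reg <- sum(rowMeans(sl1)) / n_pos
  }
  out <- list(total = cls + lambda * reg, cls = cls, reg = reg)
  if (!with_grad) return(out)

  dlogits <- numeric(n)
  pp <- p[pos]
  dlogits[pos] <- alpha * (gamma * (1 - pp)^gamma * pp * log(pp) -
                             (1 - pp)^(gamma + 1)) / n_pos
  pn <- p[neg]
  dlogits[neg] <- (1 - alpha) * (-gamma * pn^gamma * (1 - pn) * log(1 - pn) +
                                   pn^(gamma + 1)) / n_pos
  dreg <- matrix(0, n, 4L)
  if (length(pos) > 0L) {
    tgt <- as.matrix(assignment[pos, c("dz", "dy", "dx", "dd")])
    err <- flat$reg[pos, , drop = FALSE] - tgt
    dreg[pos, ] <- lambda * ifelse(abs(err) < 1, err, sign(err)) / (4 * n_pos)
  }
  level_dims <- lapply(head_out, function(a) dim(a)[1:3])
  out$grad <- unflatten_grad(dlogits, dreg, level_dims)
  out
}
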