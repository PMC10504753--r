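# Node centrality: expected influence, bridge expected influence across
# the anxiety/depression communities, nodewise predictability.

#' Expected influence of each node
#'
#' One-step expected influence: the signed sum of all edge weights
#' incident to a node. Unlike strength (which takes absolute values), EI
#' keeps signs, so inhibitory edges reduce a node's influence.
#'
#' @param net a `ggm_network`.
#' @return Named numeric vector of EI values.
#' @export
expected_influence <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  rowSums(net$weights)
}

#' Bridge expected influence of each node
#'
#' The signed sum of a node's edge weights that cross to the other
#' symptom community (anxiety vs depression), quantifying how strongly a
#' symptom links the two disorders. Together with the within-community
#' incident sum it decomposes expected influence exactly:
#' `EI(i) = bEI(i) + within(i)`.
#'
#' @param net a `ggm_network` with a community assignment for every node.
#' @return Named numeric vector of bEI values.
#' @export
bridge_expected_influence <- function(net) {
  stopifnot(inherits(net, "ggm_network"))
  comm <- net$community[net$nodes]
  if (anyNA(comm)) {
    stop("every node needs a community; missing: ",
         paste(net$nodes[is.na(comm)], collapse = ", "))
  }
  cross <- outer(comm, comm, FUN = "!=")
  rowSums(net$weights * cross)
}

#' Nodewise predictability (R-squared from neighbors)
#'
#' For each item, the proportion of variance explained by a least-squares
#' regression on all remaining items -- an upper-bound proxy for how much
#' of a symptom the rest of the network accounts for.
#'
#' @param items numeric matrix of item responses (columns named as
#'   nodes).
#' @return Named numeric vector of R-squared values in `[0, 1]`.
#' @export
predictability <- function(items) {
  items <- as.matrix(items)
  p <- ncol(items)
  stopifnot(nrow(items) >= p + 2)
  out <- numeric(p)
  for (j in seq_len(p)) {
    y <- items[, j]
    X <- cbind(1, items[, -j, drop = FALSE])
    fit <- tryCatch(qr(X), error = function(e) NULL)
    if (is.null(fit) || fit$rank < ncol(X)) {
      warning(sprintf("singular design for node %d; using ridge fallback", j))
      XtX <- crossprod(X) + diag(1e-8, ncol(X))
      beta <- solve(XtX, crossprod(X, y))
      res <- y - X %*% beta
    } else {
      res <- qr.resid(fit, y)
    }
    out[j] <- 1 - sum(res^2) / sum((y - mean(y))^2)
  }
  stats::setNames(pmin(pmax(out, 0), 1), colnames(items))
}

#' Centrality table for a network
#'
#' Expected influence, bridge expected influence, their z-standardized
#' versions, and (when item data are supplied) nodewise predictability.
#'
#' @param net a `ggm_network`.
#' @param items optional item matrix for predictability.
#' @return Data frame, one row per node.
#' @export
centrality_table <- function(net, items = NULL) {
  ei <- expected_influence(net)
  bei <- bridge_expected_influence(net)
  out <- data.frame(node = net$nodes, community = net$community[net$nodes],
                    ei = ei, z_ei = as.numeric(scale(ei)),
                    bei = bei, z_bei = as.numeric(scale(bei)),
                    stringsAsFactors = FALSE)
  if (!is.null(items)) {
    r2 <- predictability(items)
    out$predictability <- r2[net$nodes]
  }
  rownames(out) <- NULL
  out
}
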