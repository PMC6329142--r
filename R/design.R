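# Internal fixed-effect design construction shared by the twin model and the
# kinship LMM. Genotype enters either as the additive count or as the
# co-dominant pair (het, hom_minor); the exposure as a numeric column or as
# indicator columns of a factor. Interaction blocks are all pairwise (or
# triple, with time) products of the genotype and exposure columns.

.g_columns <- function(g, coding) {
  if (coding == "additive") {
    m <- cbind(G = as.numeric(g))
  } else {
    m <- codominant_coding(g)
    colnames(m) <- c("G_het", "G_hom")
  }
  m
}

.e_columns <- function(e) {
  if (is.factor(e) || is.character(e)) {
    e <- factor(e)
    if (nlevels(e) < 2) stop("exposure has a single level")
    m <- stats::model.matrix(~e)[, -1, drop = FALSE]
    colnames(m) <- paste0("E_", levels(e)[-1])
    m
  } else {
    cbind(E = as.numeric(e))
  }
}

.product_block <- function(a, b, sep = ":") {
  out <- matrix(NA_real_, nrow(a), ncol(a) * ncol(b))
  nm <- character(ncol(a) * ncol(b))
  k <- 0
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    k <- k + 1
    out[, k] <- a[, i] * b[, j]
    nm[k] <- paste(colnames(a)[i], colnames(b)[j], sep = sep)
  }
  colnames(out) <- nm
  out
}

# returns list(X, terms): X has an intercept; terms maps term labels to
# column index vectors
.ge_design <- function(data, coding, covariates, time = NULL, timeseg = NULL,
                       gte = FALSE) {
  Gm <- .g_columns(data$genotype, coding)
  Em <- .e_columns(data$exposure)
  blocks <- list(`(Intercept)` = cbind(`(Intercept)` = rep(1, nrow(data))))
  for (cv in covariates) {
    m <- cbind(as.numeric(data[[cv]]))
    colnames(m) <- cv
    blocks[[cv]] <- m
  }
  if (!is.null(time)) {
    blocks[["T"]] <- cbind(T = time)
    blocks[["Tseg"]] <- cbind(Tseg = timeseg)
  }
  blocks[["G"]] <- Gm
  blocks[["E"]] <- Em
  if (gte) {
    Tm <- cbind(T = time)
    blocks[["G:T"]] <- .product_block(Gm, Tm)
    blocks[["E:T"]] <- .product_block(Em, Tm)
    blocks[["G:E"]] <- .product_block(Gm, Em)
    blocks[["G:E:T"]] <- .product_block(.product_block(Gm, Em), Tm)
  } else {
    blocks[["G:E"]] <- .product_block(Gm, Em)
  }
  X <- do.call(cbind, blocks)
  idx <- split(seq_len(ncol(X)), rep(seq_along(blocks),
                                     vapply(blocks, ncol, 1L)))
  terms <- stats::setNames(idx, names(blocks))
  # fix colnames lost by single-column cbind
  colnames(X) <- unlist(lapply(blocks, colnames))
  list(X = X, terms = terms)
}

.check_full_rank <- function(X) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is singular; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
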