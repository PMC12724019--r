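#' Common average reference for subdural channels
#'
#' Subtracts the per-sample mean across included subdural channels from each
#' channel. Excluded (artifact / white-matter / out-of-brain) channels must
#' be removed before calling: they contribute neither to the reference nor
#' to the output.
#'
#' @param x Numeric matrix, samples x channels (subdural, included only).
#' @return Matrix of the same shape; the cross-channel mean of every row
#'   is zero.
#' @export
common_average_reference <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2L)
    stop("common average reference requires at least 2 included channels")
  x - rowMeans(x)
}

#' Bipolar pairs along a depth electrode shaft
#'
#' Pair k is contact k minus contact k+1, ordered along the shaft; a shaft
#' with n contacts yields n - 1 pair signals.
#'
#' @param x Numeric matrix, samples x contacts, columns in shaft order.
#' @return Matrix samples x (n - 1) pairs; column names `"c1-c2"` style when
#'   the input has column names.
#' @export
bipolar_pairs <- function(x) {
  x <- as.matrix(x)
  n <- ncol(x)
  if (n < 2L) stop("bipolar montage requires a shaft with >= 2 contacts")
  p <- x[, -n, drop = FALSE] - x[, -1L, drop = FALSE]
  if (!is.null(colnames(x)))
    colnames(p) <- paste0(colnames(x)[-n], "-", colnames(x)[-1L])
  p
}

#' Map per-pair values back to a depth contact
#'
#' A bipolar-montage statistic is assigned to each contact as the mean of
#' the values of its adjacent pairs: interior contacts have two flanking
#' pairs, shaft-end contacts inherit their single adjacent pair's value.
#'
#' @param pair_values Numeric vector of per-pair values in shaft order
#'   (length = contacts - 1).
#' @param contact_index Integer contact position along the shaft (1-based).
#' @return Scalar contact value.
#' @export
contact_value_from_pairs <- function(pair_values, contact_index) {
  n_pairs <- length(pair_values)
  n_contacts <- n_pairs + 1L
  stopifnot(contact_index >= 1L, contact_index <= n_contacts)
  if (n_pairs < 1L) stop("contact has no adjacent pairs")
  adj <- c(contact_index - 1L, contact_index)
  adj <- adj[adj >= 1L & adj <= n_pairs]
  mean(pair_values[adj])
}

#' Apply the study montage to a recording
#'
#' Subdural channels receive a common average reference (computed over
#' included subdural channels only); each depth shaft is converted to
#' bipolar pair signals. Excluded channels are dropped first.
#'
#' @param signals Numeric matrix samples x channels, columns named.
#' @param electrodes Electrode metadata `data.frame` with columns `name`,
#'   `kind` ("subdural"/"depth"), `shaft_id`, `contact_index`, `excluded`
#'   (plus any label flags, which are carried through untouched).
#' @return List with `signals` (montaged matrix, columns = montage channels),
#'   `channels` (`data.frame`: montage channel name, kind, and for pairs the
#'   shaft + flanking contact names) and `electrodes` (included rows of the
#'   input metadata).
#' @export
apply_montage <- function(signals, electrodes) {
  stopifnot(is.matrix(signals), !is.null(colnames(signals)))
  el <- electrodes[!electrodes$excluded, , drop = FALSE]
  missing_cols <- setdiff(el$name, colnames(signals))
  if (length(missing_cols))
    stop("signals missing for channels: ", paste(missing_cols, collapse = ", "))

  out_sig <- list(); out_meta <- list()
  sub <- el[el$kind == "subdural", , drop = FALSE]
  if (nrow(sub) >= 2L) {
    car <- common_average_reference(signals[, sub$name, drop = FALSE])
    out_sig[[length(out_sig) + 1L]] <- car
    out_meta[[length(out_meta) + 1L]] <- data.frame(
      channel = sub$name, kind = "subdural",
      shaft_id = NA_character_, contact_a = sub$name, contact_b = NA_character_,
      stringsAsFactors = FALSE)
  } else if (nrow(sub) == 1L) {
    stop("common average reference requires at least 2 included channels")
  }
  dep <- el[el$kind == "depth", , drop = FALSE]
  if (nrow(dep)) {
    for (sh in unique(dep$shaft_id)) {
      shaft <- dep[dep$shaft_id == sh, , drop = FALSE]
      shaft <- shaft[order(shaft$contact_index), , drop = FALSE]
      bp <- bipolar_pairs(signals[, shaft$name, drop = FALSE])
      out_sig[[length(out_sig) + 1L]] <- bp
      out_meta[[length(out_meta) + 1L]] <- data.frame(
        channel = colnames(bp), kind = "pair",
        shaft_id = sh,
        contact_a = shaft$name[-nrow(shaft)], contact_b = shaft$name[-1L],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out_sig)) stop("no included channels to montage")
  list(signals = do.call(cbind, out_sig),
       channels = do.call(rbind, out_meta),
       electrodes = el)
}

#' Map per-montage-channel values back to electrode contacts
#'
#' Subdural montage channels map to themselves; depth contacts receive the
#' mean of their adjacent bipolar-pair values (single pair at shaft ends),
#' via [contact_value_from_pairs].
#'
#' @param values Named numeric vector, one value per montage channel.
#' @param montage Result of [apply_montage].
#' @return Named numeric vector over included electrode contacts.
#' @export
contact_values <- function(values, montage) {
  ch <- montage$channels
  stopifnot(all(ch$channel %in% names(values)))
  el <- montage$electrodes
  out <- stats::setNames(rep(NA_real_, nrow(el)), el$name)
  sub <- ch[ch$kind == "subdural", , drop = FALSE]
  out[sub$contact_a] <- values[sub$channel]
  pair <- ch[ch$kind == "pair", , drop = FALSE]
  if (nrow(pair)) {
    for (sh in unique(pair$shaft_id)) {
      pp <- pair[pair$shaft_id == sh, , drop = FALSE]
      pv <- values[pp$channel]
      contacts <- c(pp$contact_a, pp$contact_b[nrow(pp)])
      for (k in seq_along(contacts))
        out[contacts[k]] <- contact_value_from_pairs(pv, k)
    }
  }
  out
}
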