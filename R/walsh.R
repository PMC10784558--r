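#' Hadamard matrix over {0,1} by the doubling recursion
#'
#' Builds the order-`n` Hadamard matrix with the base case `H_1 = [0]`
#' and the recursion that tiles `H_N` three times and its logical
#' complement in the lower-right block. Under the mapping
#' `b -> (-1)^b` any two distinct rows are orthogonal.
#'
#' @param order Matrix order, a power of two (>= 1).
#' @return Integer matrix of 0/1 entries, `order` x `order`.
#' @export
#' @examples
#' hadamard(2)  # rbind(c(0,0), c(0,1))
hadamard <- function(order) {
  order <- as.integer(order)
  if (order < 1L || bitwAnd(order, order - 1L) != 0L) {
    stop("'order' must be a power of two")
  }
  H <- matrix(0L, 1L, 1L)
  while (nrow(H) < order) {
    H <- rbind(cbind(H, H), cbind(H, 1L - H))
  }
  H
}

#' Walsh codebook for multiclass labels
#'
#' Takes the first `num_classes` rows of the order-`order` Hadamard
#' matrix as codewords. At order 8 any two distinct codewords are at
#' Hamming distance 4, so single-bit errors are always corrected.
#'
#' @param num_classes Number of classes (<= `order`).
#' @param order Codeword length, a power of two (default 8).
#' @return A `walsh_codebook` with `codewords` (matrix, one row per
#'   class), `num_classes` and `order`.
#' @export
walsh_codebook <- function(num_classes = 5L, order = 8L) {
  num_classes <- as.integer(num_classes)
  stopifnot(num_classes >= 1L)
  H <- hadamard(order)
  if (num_classes > nrow(H)) stop("'num_classes' must not exceed 'order'")
  structure(
    list(
      codewords = H[seq_len(num_classes), , drop = FALSE],
      num_classes = num_classes,
      order = as.integer(order)
    ),
    class = "walsh_codebook"
  )
}

#' Encode a class index as its Walsh codeword
#'
#' @param class_index 0-based class index in `[0, num_classes)`.
#' @param codebook A [walsh_codebook()].
#' @return Integer 0/1 vector of length `codebook$order`.
#' @export
walsh_encode <- function(class_index, codebook) {
  stopifnot(inherits(codebook, "walsh_codebook"))
  class_index <- as.integer(class_index)
  if (class_index < 0L || class_index >= codebook$num_classes) {
    stop("'class_index' out of range")
  }
  codebook$codewords[class_index + 1L, ]
}

#' Decode soft outputs to the nearest codeword
#'
#' Returns the class whose codeword minimizes squared Euclidean distance
#' to the soft outputs (for binary outputs this is Hamming decoding
#' after 0.5-thresholding). Ties break deterministically toward the
#' lowest class index. Set `hard = TRUE` to threshold at 0.5 first and
#' decode by Hamming distance.
#'
#' @param soft_outputs Numeric vector of per-bit scores in `[0, 1]`,
#'   length `codebook$order`.
#' @param codebook A [walsh_codebook()].
#' @param hard Use hard-threshold Hamming decoding (default `FALSE`).
#' @return List with `class_index` (0-based) and `distance` (squared
#'   Euclidean, or Hamming when `hard`).
#' @export
walsh_decode <- function(soft_outputs, codebook, hard = FALSE) {
  stopifnot(inherits(codebook, "walsh_codebook"))
  y <- as.numeric(soft_outputs)
  if (length(y) != codebook$order) {
    stop("'soft_outputs' length must equal the codeword length")
  }
  if (hard) y <- as.numeric(y >= 0.5)
  d2 <- rowSums(sweep(codebook$codewords, 2L, y, "-")^2)
  k <- which.min(d2)  # which.min takes the first minimum: lowest index
  list(class_index = k - 1L, distance = unname(d2[k]))
}
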