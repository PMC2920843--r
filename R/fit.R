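# Mass-weighted rigid-body superposition (Kabsch).

kabsch_fit <- function(mobile, ref, w) {
  cm <- colSums(mobile * w) / sum(w)
  cr <- colSums(ref * w) / sum(w)
  a <- sweep(mobile, 2, cm)
  b <- sweep(ref, 2, cr)
  h <- t(a * w) %*% b
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(rotation = rot, shift_mobile = cm, shift_ref = cr)
}

apply_fit <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$shift_mobile) %*% t(fit$rotation), 2,
        fit$shift_ref, "+")
}

# Superpose all frames of an (n x 3 x f) array onto their iteratively
# refined mean structure, weighting by `w` (masses). Fitting uses the atoms
# in `fit_sel`; the transform is applied to all atoms.
superpose_frames <- function(arr, w, fit_sel = NULL, iterations = 3) {
  nf <- dim(arr)[3]
  fit_sel <- fit_sel %||% seq_len(dim(arr)[1])
  ws <- w[fit_sel]
  ref <- arr[, , 1, drop = TRUE]
  for (it in seq_len(iterations)) {
    for (f in seq_len(nf)) {
      ft <- kabsch_fit(arr[fit_sel, , f, drop = TRUE],
                       ref[fit_sel, , drop = FALSE], ws)
      arr[, , f] <- apply_fit(arr[, , f, drop = TRUE], ft)
    }
    ref <- apply(arr, c(1, 2), mean)
  }
  arr
}
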