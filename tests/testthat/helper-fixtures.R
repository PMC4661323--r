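# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env))
    assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# a noiseless single-subject phantom at the default grid
noiseless_subject <- function() {
  fixture("noiseless_subject", function() {
    spec <- phantom_spec(snr = list(mpm = Inf, dwi = Inf), n_subjects = 2,
                         seed = 42)
    generate_subject(spec, 1)
  })
}

noiseless_pipeline <- function() {
  fixture("noiseless_pipeline", function() {
    s <- noiseless_subject()
    roi <- as.logical(s$reference_roi)
    anchor <- mean(as.numeric(s$truth$g)[roi])
    list(subject = s, result = gratio_pipeline(s, g_reference = anchor),
         anchor = anchor)
  })
}

# forward single-tensor diffusion signals on a tiny grid
tiny_dwi <- function(D, s0 = 1000, dim3 = c(3, 3, 3), snr = Inf,
                     seed = 1) {
  grad <- gratiomap:::phantom_gradient_scheme()
  q <- rowSums((grad$bvecs %*% D) * grad$bvecs)
  sig <- s0 * exp(-grad$bvals * q)
  vols <- array(rep(sig, each = prod(dim3)), c(dim3, length(sig)))
  if (is.finite(snr)) {
    set.seed(seed)
    vols <- add_rician_noise(vols, s0 / snr)
  }
  dwi_series(vols, grad$bvals, grad$bvecs, diag(c(2.3, 2.3, 2.3, 1)))
}

diag_tensor <- function(l1, l2, l3) diag(c(l1, l2, l3))

# forward FLASH triplet from known parameter maps
forward_mpm <- function(a_app, r1, mt_pu, n_echoes = 2L,
                        affine = diag(4)) {
  prot <- mpm_protocol()
  mk <- function(w, mt) {
    s <- flash_signal(a_app, r1, prot[[w]]$flip_angle, prot[[w]]$tr,
                      mt_sat = mt)
    flash_stack(array(rep(as.numeric(s), n_echoes), c(dim(s), n_echoes)),
                prot[[w]]$flip_angle, prot[[w]]$tr,
                (1:n_echoes) * 2.46e-3, affine)
  }
  mpm_acquisition(pdw = mk("pdw", 0), t1w = mk("t1w", 0),
                  mtw = mk("mtw", mt_pu))
}
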