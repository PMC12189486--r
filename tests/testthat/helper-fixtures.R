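# Shared fixtures, memoized so expensive runs happen once per test session.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# easy-separation study fixture: 40 cycles/class, murmur SNR 15 dB
easy_spec <- function() {
  dataset_spec(counts = c(normal = 40, systolic = 40, diastolic = 40,
                          abnormal = 40),
               seed = 11, snr_range = c(15, 15))
}

easy_cycles <- function() memo("easy_cycles", generate_dataset(easy_spec()))

# scaled-down head profile used throughout the tests (8 heads kept, key
# dimension reduced for the 196-token tiny backbone)
tiny_mha <- function() head_config("mha", mha_key_dim = 32)

easy_model <- function(variant = "baseline") {
  memo(paste0("easy_model_", variant), {
    hd <- if (variant == "mha") tiny_mha() else head_config(variant)
    fit_pcg_classifier(easy_cycles(), head = hd,
                       train = train_config(seed = 3, max_epochs = 150))
  })
}

# minimal dataset / model for contract tests where accuracy is irrelevant
small_cycles <- function() {
  memo("small_cycles",
       generate_dataset(dataset_spec(counts = c(normal = 6, systolic = 6,
                                                diastolic = 6, abnormal = 6),
                                     seed = 21)))
}

small_model <- function() {
  memo("small_model",
       fit_pcg_classifier(small_cycles(),
                          train = train_config(seed = 8, max_epochs = 4,
                                               patience = 4)))
}

# random small feature map + head for gradient checks
random_head_case <- function(seed, variant = "baseline", dims = c(6, 6, 8)) {
  set.seed(seed)
  A <- array(rnorm(prod(dims)), dim = dims)
  hd <- switch(variant,
               baseline = head_config("baseline", dense_sizes = c(16, 8)),
               se = head_config("se", se_ratio = 4,
                                dense_sizes = c(16, 8)),
               mha = head_config("mha", mha_heads = 2, mha_key_dim = 4,
                                 dense_sizes = c(16, 8)))
  params <- heartcam:::head_init(hd, dims[3], seed = seed + 1000)
  bn <- heartcam:::head_bn_states(hd)
  list(A = A, head = hd, params = params, bn = bn)
}

# head logit for a class as a pure function of the feature map (eval mode)
head_logit <- function(case, A, class_index) {
  fw <- heartcam:::head_forward(case$params, case$head, list(A),
                                training = FALSE, case$bn)
  fw$logits[1, class_index]
}

# analytic gradient of that logit w.r.t. the feature map
head_logit_grad <- function(case, A, class_index) {
  fw <- heartcam:::head_forward(case$params, case$head, list(A),
                                training = FALSE, case$bn)
  dL <- matrix(0, 1, case$head$n_classes)
  dL[1, class_index] <- 1
  bw <- heartcam:::head_backward(case$params, case$head, fw, dL,
                                 want_dA = TRUE)
  bw$dA_list[[1]]
}
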