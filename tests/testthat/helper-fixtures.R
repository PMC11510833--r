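# Shared fixtures: all tiny, all generated in code.

rnd_x <- function(c, h, w, n = 1, seed = 1) {
  set.seed(seed)
  array(rnorm(c * h * w * n), c(c, h, w, n))
}

# forward a single module on a (C, H, W, N) array, returning the value
fwd <- function(m, x, training = FALSE) {
  ag_v <- yoloev:::ag_v
  ag_v(yoloev:::ev_forward(m, yoloev:::ag_const(x),
                           list(training = training)))
}

# set every array of a module tree to a constant (0 freezes convs; norm
# scale stays at its init unless included)
zero_module <- function(m, what = "w") {
  for (p in yoloev:::collect_pars(m)) {
    if (length(dim(p$value)) == 4L || what == "all") p$value[] <- 0
  }
  m
}

tiny_samples <- function(n = 4, imgsz = 64, n_classes = 3, seed_base = 0) {
  sp <- scene_params(image_size = imgsz, n_classes = n_classes)
  lapply(seq_len(n), function(i) {
    s <- generate_scene(sp, seed = seed_base + i)
    list(image = s$image, boxes = s$boxes, cls = s$cls)
  })
}
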