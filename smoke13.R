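library(stairgait)
w <- generate_walk(walk_specs(rep("level", 4)), noise = noise_params(0, 0), seed = 4)
tb <- w$truth$left$body; tr <- w$truth$left; fs <- w$fs
th <- tr$theta_deg * pi/180
f_pa <- tb$acc[,2]*9.81; f_si <- tb$acc[,3]*9.81
aw_x <- cos(th)*f_pa - sin(th)*f_si
b <- tr$borders; i0 <- b[2]; i1 <- b[3]; idx <- (i0+1):(i1+1); dt <- 1/fs
# compare integrated velocity vs truth velocity across the stride
trap <- function(a) cumsum((a + c(a[1], head(a,-1)))/2)*dt - a[1]*dt
vx_t <- trap(aw_x[idx])
verr <- vx_t - (tr$velocity[idx,1] - tr$velocity[idx[1],1])
cat("max verr:", max(abs(verr)), " end verr:", verr[length(verr)], "\n")
# where does verr jump
j <- which(abs(diff(verr)) > 1e-4)
cat("jump samples (rel):", head(j, 20), "\n")
cat("stride len:", length(idx), "\n")
print(cbind(rel=j, verr_before=verr[j], verr_after=verr[j+1])[1:10,])
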