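library(stairgait)
w <- generate_walk(walk_specs(rep("level", 4)), noise = noise_params(0, 0), seed = 4)
tb <- w$truth$left$body; tr <- w$truth$left; fs <- w$fs
th <- tr$theta_deg * pi/180
f_pa <- tb$acc[,2]*9.81; f_si <- tb$acc[,3]*9.81
aw_x <- cos(th)*f_pa - sin(th)*f_si
aw_z <- sin(th)*f_pa + cos(th)*f_si - 9.81
# compare vs derivative of truth velocity (central diff)
vx <- tr$velocity[,1]
ax_num <- c(0, diff(vx, lag=2)/2, 0) * fs
err <- aw_x[3:(length(vx)-2)] - ax_num[3:(length(vx)-2)]
cat("max |aw_x - dv/dt|:", max(abs(err)), "\n")
bad <- which(abs(err) > 1)
cat("bad sample region:", range(bad)+2, " border2:", tr$borders[2], "\n")
# plot-ish: print a few values around worst
i <- which.max(abs(err)) + 2
print(cbind(idx=(i-4):(i+4), aw_x=aw_x[(i-4):(i+4)], ax_num=ax_num[(i-4):(i+4)]))
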