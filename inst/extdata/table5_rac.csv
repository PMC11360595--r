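site_id,depth_cm,element,rac_percent
J11,5,As,0.5
J11,5,Hg,10.5
J11,10,As,1.3
J11,10,Hg,9.8
J13,5,As,0.5
J13,5,Hg,7.7
J13,10,As,0.5
J13,10,Hg,4.5
J13,15,As,0.5
J13,15,Hg,10.7
J13,20,As,0.8
J13,20,Hg,5.6
J13,25,As,0.8
J13,25,Hg,5.5
K12,5,As,0.2
K12,5,Hg,6.3
K12,10,As,0.4
K12,10,Hg,5.1
K12,15,As,0.4
K12,15,Hg,10.3
L11,5,As,0.6
L11,5,Hg,4.1
L11,10,As,0.4
L11,10,Hg,10.2
L11,15,As,0.5
L11,15,Hg,7.6
M12,5,As,0.6
M12,5,Hg,13.1
M12,10,As,0.8
M12,10,Hg,6.1
M12,15,As,0.6
M12,15,Hg,6.6
M14,5,As,0.5
M14,5,Hg,3.5
M14,10,As,0.8
M14,10,Hg,8.2
M14,15,As,0.4
M14,15,Hg,6.7
N13,5,As,1.5
N13,5,Hg,6.6
N13,10,As,2.0
N13,10,Hg,9.4
N13,15,As,1.5
N13,15,Hg,2.6
N13,20,As,3.2
N13,20,Hg,7.5
P9,5,As,1.8
P9,5,Hg,15.8
P9,10,As,1.3
P9,10,Hg,2.5
P9,15,As,3.7
P9,15,Hg,8.4
P11,5,As,2.2
P11,5,Hg,3.8
P11,10,As,1.7
P11,10,Hg,13.1
Q8,5,As,2.8
Q8,5,Hg,5.8
Q8,10,As,2.3
Q8,10,Hg,7.1
Q8,15,As,2.1
Q8,15,Hg,10.6
Q8,20,As,2.5
Q8,20,Hg,12.5
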