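{"n_subjects":735,"seed":1,"unassigned_r":0.1,"blocks":[{"label":"A-1","members":[1,7,8,10,24,26,53,54,56,59],"within_r":0.92,"between_r":0.2},{"label":"A-2","members":[3,9,20,27,32,33],"within_r":0.9,"between_r":0.2},{"label":"B","members":[25,52,65],"within_r":0.88,"between_r":0.2},{"label":"C","members":[4,16,17,23],"within_r":0.9,"between_r":0.2},{"label":"D","members":[60,61,63,64],"within_r":0.94,"between_r":0.2},{"label":"E","members":[5,12,13,18,19,30,36,37,41,51],"within_r":0.86,"between_r":0.2},{"label":"F","members":[39,42,48],"within_r":0.9,"between_r":0.2},{"label":"G","members":[47,49,55],"within_r":0.92,"between_r":0.2},{"label":"H","members":[21,22,57,58],"within_r":0.88,"between_r":0.2},{"label":"I","members":[11,28,29,44,45],"within_r":0.9,"between_r":0.2}],"means":[3.47234356488398,1.78684922906462,117.681061568485,-0.220815662653597,23.1314208146275,26.0163585645396,-2.18866833367345,0.950342829095051,23.263185502643,1.26491106406735,89.5081160591976,87.179313728571,23.5121686622856,0.380747847658085,128.163504987128,-0.449863396090961,-2.31124712983407,58.9800019790882,9.52258298495201,76.0104143226664,82.1626541494991,81.3404619601243,0.822192189374874,1.07964850225116,39.5056163249627,-0.996815278536126,21.9911299171771,2.0335031682137,-3.03031844674982,16.6610822797193,-4.58724739058186,90,66.4878313377144,120.650667957053,138.576334374997,131.423665625003,390.650667957053,70.178344238091,40.2492235949962,54.6641855401899,76.7594800848128,50.6951674225463,0.793945964504216,67.0820393249937,0.955879481815749,117.1537451386,127.941392832812,85.146931829632,120.933866224478,0.704078472704922,10.7294250394587,121.668270474462,0.799352698806022,-2.34947865063427,68.2495421230062,-2.21359436211787,-0.74560700082611,-0.971951983219751,0.878751108116488,69.6717102560091,69.290962408351,87.5776167770216,157.249327033031,156.050450410795,128.806769769229],"sds":[2.5,2.5,5,2.5,5,2.5,2.5,2.5,5,2.5,5,5,5,5,5,5,5,5,5,5,5,5,5,2.5,5,2.5,5,2.5,2.5,5,2.5,5,5,5,5,5,5,2.5,2.5,5,5,2.5,0.05,2.5,0.05,2.5,2.5,2.5,2.5,0.05,5,5,2.5,2.5,2.5,2.5,2.5,2.5,2.5,5,5,5,5,6,5],"variable_names":["Incisor overjet","Incisor overbite","Interincisal angle","Convexity of point A","Lower facial height","Upper molar to PTV","L1 to A-Pog","U1 to A-Pog","L1 inclination","Lower lip to E-plane","Facial angle","Facial axis","FMA","Palatal plane angle","Mandibular Arc","Facial convexity","A-B plane angle","Y axis","Occlusal plane angle","L1 to Occlusal plane angle","SNA","SNB","ANB","U1 to NA","U1 to NA Angle","L1 to NB","L1 to NB Angle","Pog to NB","Pog & L1 to NB (diff.)","Occlusal Plane to SN","Wits Appraisal","IMPA","FMIA","Saddle angle","Articular angle","Gonion angle","Sum","Anterior cranial base","Posterior cranial base","Upper gonial angle","Lower gonial angle","Ramus height","Posterior cranial base to ramus ratio","Mandibular body length","Body to anterior cranial base ratio","Facial depth","Facial length on Y-axis","Posterior facial height","Anterior facial height","Posterior to anterior facial height ratio","Occlusal plane to GoGn","U1 to SN angle","U1 to facial plane","L1 to facial plane","Lower anterior facial height","Upper Lip to E-Plane","Nasion perpendicular to point A","Pog-N perpendicular","U1 to A vertical","ODI","A-B to mandibular plane","APDI","Combination factor","Extraction Index","U1 to FH plane"]}
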